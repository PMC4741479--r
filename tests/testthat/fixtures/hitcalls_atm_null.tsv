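mirna_id	genotype	fc	sd	call	effect	threshold_used
hsa-let-7e	ATM_null	1.42886	0.033500000000000002	up	0.42886000000000002	0.067000000000000004
hsa-let-7f	ATM_null	1.62202	0.034099999999999998	up	0.62202000000000002	0.068199999999999997
hsa-let-7g	ATM_null	1.0788800000000001	0.047	unchanged	0.078880000000000061	0.094
hsa-mir-016	ATM_null	2.2489599999999998	0.1462	up	1.2489599999999998	0.29239999999999999
hsa-mir-019a	ATM_null	0.91168000000000005	0.0298	down	-0.088319999999999954	0.0596
hsa-mir-019b	ATM_null	0.92420000000000002	0.060999999999999999	unchanged	-0.075799999999999979	0.122
hsa-mir-020a	ATM_null	0.82157999999999998	0.19139999999999999	unchanged	-0.17842000000000002	0.38279999999999997
hsa-mir-027a	ATM_null	1.4020699999999999	0.0356	up	0.40206999999999993	0.071199999999999999
hsa-mir-029b	ATM_null	1.56938	0.17749999999999999	up	0.56938	0.35499999999999998
hsa-mir-029c	ATM_null	1.2067300000000001	0.1883	unchanged	0.20673000000000008	0.37659999999999999
hsa-mir-030c	ATM_null	1.60287	0.12570000000000001	up	0.60287000000000002	0.25140000000000001
hsa-mir-030e 3p	ATM_null	0	0	undetected	NA	0
hsa-mir-101	ATM_null	0.73823000000000005	0.051700000000000003	down	-0.26176999999999995	0.10340000000000001
hsa-mir-106a	ATM_null	1.92872	0.067799999999999999	up	0.92871999999999999	0.1356
hsa-miR-1248	ATM_null	0	0	undetected	NA	0
hsa-miR-1254	ATM_null	0	0	undetected	NA	0
hsa-miR-1308	ATM_null	1.0638300000000001	0.097000000000000003	unchanged	0.063830000000000053	0.19400000000000001
hsa-mir-142 3p	ATM_null	0.83335000000000004	0.1186	unchanged	-0.16664999999999996	0.23719999999999999
hsa-mir-150	ATM_null	0	0	undetected	NA	0
hsa-miR-1826	ATM_null	3.1104699999999998	0.083199999999999996	up	2.1104699999999998	0.16639999999999999
hsa-miR-18b	ATM_null	0.86414999999999997	0.026100000000000002	down	-0.13585000000000003	0.052200000000000003
hsa-miR-320c	ATM_null	0	0.036799999999999999	down	-1	0.073599999999999999
hsa-mir-565-Pre	ATM_null	1.02796	0.0482	unchanged	0.027959999999999985	0.0964
hsa-mir-566-Pre	ATM_null	1.2985500000000001	0.14710000000000001	up	0.29855000000000009	0.29420000000000002
hsa-mir-595	ATM_null	0	0	undetected	NA	0
hsa-miR-768-3p	ATM_null	0	0	undetected	NA	0
hsa-miR-768-5p	ATM_null	0	0	undetected	NA	0
hsa-miR-886-5p	ATM_null	0.76209000000000005	0.030499999999999999	down	-0.23790999999999995	0.060999999999999999
# summary: n_up=9 n_down=5 n_altered=14 n_unchanged=7 n_undetected=7
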