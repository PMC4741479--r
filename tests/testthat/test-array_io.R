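test_that("a minimal probe table reads into triplicate spots", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tblock\trow\tcol\tF635\tF532\tcontrol_class",
               "hsa-mir-016\t1\t1\t1\t100\t90\tprobe",
               "hsa-mir-016\t1\t1\t2\t110\t91\tprobe",
               "hsa-mir-016\t1\t1\t3\t120\t92\tprobe"), path)
  cond <- read_array_table(path, "GM0536", "ATM_wt", "mock", 0)
  expect_s3_class(cond, "array_condition")
  expect_equal(nrow(cond$spots), 3)
  expect_equal(cond$spots$replicate_index, 1:3)
  expect_equal(cond$spots$signal_f635, c(100, 110, 120))
})

test_that("malformed probe tables are rejected with located errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tblock\trow\tcol\tF635\tF532\tcontrol_class",
               "m1\t1\t1\t1\t-5\t10\tprobe"), path)
  expect_error(read_array_table(path, "GM0536", "ATM_wt", "mock", 0),
               "negative intensity.*row 1")

  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tblock\trow\tF635\tF532\tcontrol_class",
               "m1\t1\t1\t5\t10\tprobe"), path2)
  expect_error(read_array_table(path2, "GM0536", "ATM_wt", "mock", 0), "col")

  path3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tblock\trow\tcol\tF635\tF532\tcontrol_class",
               "m1\t1\t1\t1\t5\t10\tspikein"), path3)
  expect_error(read_array_table(path3, "GM0536", "ATM_wt", "mock", 0),
               "control_class")
})

test_that("array condition invariants are enforced", {
  spots <- data.frame(gene_id = c("a", "a"), block = 1L, row = 1L,
                      col = c(1L, 1L), replicate_index = 1:2,
                      signal_f635 = c(1, 2), signal_f532 = c(1, 2),
                      control_class = "probe")
  expect_error(array_condition("GM0536", "ATM_wt", "mock", 0, spots),
               "duplicate")
  spots$col <- 1:2
  expect_error(array_condition("GM0536", "ATM_wt", "mock", 3, spots),
               "dose")
})

test_that("array tables round-trip bit-identically", {
  set.seed(101)
  for (rep in 1:5) {
    n <- sample(3:8, 1)
    genes <- setNames(
      lapply(seq_len(n + 2), function(i) runif(3, 0, 5000)),
      c(sprintf("m%02d", seq_len(n)), "pos-u6", "neg-gnd"))
    cond <- make_condition(genes)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_array_table(cond, path)
    back <- read_array_table(path, cond$cell_line, cond$genotype,
                             cond$treatment, cond$dose)
    expect_equal(back$spots, cond$spots, tolerance = 0)
  }
})

test_that("the packaged screen fixture parses to 28 ordered records", {
  s <- invitro_screen()
  expect_equal(nrow(s), 28)
  expect_equal(anyDuplicated(s$mirna_id), 0)
  r16 <- s[s$mirna_id == "hsa-mir-016", ]
  expect_equal(r16$fc_wt, 0.88144)
  expect_equal(r16$sd_wt, 0.1411)
  expect_equal(r16$fc_null, 2.24896)
  expect_equal(r16$sd_null, 0.1462)
  expect_equal(s$mirna_id[1], "hsa-let-7e")
})

test_that("screen-table validation catches duplicates and bad cells", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mirna_id\tfc_wt\tsd_wt\tfc_null\tsd_null",
               "m1\t1\t0\t1\t0", "m1\t2\t0\t2\t0"), path)
  expect_error(read_screen_table(path), "duplicate")

  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mirna_id\tfc_wt\tsd_wt\tfc_null\tsd_null",
               "m1\tx\t0\t1\t0"), path2)
  expect_error(read_screen_table(path2), "non-numeric.*fc_wt")

  path3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("mirna_id\tfc_wt\tsd_wt\tfc_null\tsd_null", path3)
  expect_equal(nrow(read_screen_table(path3)), 0)
})

test_that("screen tables round-trip exactly", {
  s <- invitro_screen()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_screen_table(s, path)
  expect_equal(read_screen_table(path), s, tolerance = 0)
})

test_that("cohort tables validate group labels and missing cells", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("patient_id\tgroup\tmir-a\tmir-b",
               "p1\tresponder\t5\t1",
               "p2\tprogressor\t6\t2",
               "p3\tuntreated\t7\t3"), path)
  coh <- read_cohort_table(path)
  expect_equal(nrow(coh), 3)
  expect_equal(coh$`mir-a`, c(5, 6, 7))

  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("patient_id\tgroup\tmir-a",
               "p1\tradiated\t5"), path2)
  expect_error(read_cohort_table(path2),
               "responder, progressor, untreated")

  path3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("patient_id\tgroup\tmir-a",
               "p1\tresponder\tNA",
               "p2\tprogressor\t2",
               "p3\tuntreated\t3"), path3)
  expect_error(read_cohort_table(path3), "missing expression")
  permissive <- read_cohort_table(path3, strict = FALSE)
  expect_true(is.na(permissive$`mir-a`[1]))
})

test_that("simulated cohorts round-trip through the cohort table format", {
  sim <- simulate_cohort(cohort_sim_config(seed = 11, n_per_group = 4))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort_table(sim$cohort, path)
  back <- read_cohort_table(path)
  expect_equal(back, sim$cohort, tolerance = 0)
})
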