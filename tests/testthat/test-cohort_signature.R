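test_that("group ratios are means over the untreated mean", {
  coh <- make_cohort(list(
    responder = list(m1 = c(18, 20, 22)),
    progressor = list(m1 = c(4, 5, 6)),
    untreated = list(m1 = c(9, 10, 11))))
  r <- group_ratios(coh, pseudo = 0, log_transform = FALSE)
  expect_equal(r$ratio_responder, 2.0)
  expect_equal(r$ratio_progressor, 0.5)
  expect_equal(r$n_responder, 3)
  expect_equal(r$n_untreated, 3)

  flat <- make_cohort(list(responder = list(m1 = c(5, 5, 5)),
                           progressor = list(m1 = c(5, 5, 5)),
                           untreated = list(m1 = c(5, 5, 5))))
  rf <- group_ratios(flat, pseudo = 0)
  expect_equal(rf$ratio_responder, 1)
  expect_equal(rf$ratio_progressor, 1)
  expect_equal(rf$p_value, 1)
})

test_that("the responder-progressor test matches the closed-form Welch t", {
  coh <- make_cohort(list(responder = list(m1 = c(1, 2, 3)),
                          progressor = list(m1 = c(2, 3, 4)),
                          untreated = list(m1 = c(1, 1, 1))))
  r <- group_ratios(coh, pseudo = 0, log_transform = FALSE)
  # equal variances, n = 3 each: t = -1.2247 on df 4
  expect_equal(r$p_value, 0.287864, tolerance = 1e-4)
  expect_equal(r$p_value, welch_p_oracle(c(1, 2, 3), c(2, 3, 4)),
               tolerance = 1e-12)
})

test_that("a missing patient group is reported by name", {
  coh <- make_cohort(list(responder = list(m1 = 1:3),
                          untreated = list(m1 = 1:3)))
  expect_error(group_ratios(coh), "progressor")
})

test_that("ratios converge to plain mean ratios as the pseudocount vanishes", {
  coh <- make_cohort(list(responder = list(m1 = c(18, 20, 22)),
                          progressor = list(m1 = c(4, 5, 6)),
                          untreated = list(m1 = c(9, 10, 11))))
  r0 <- group_ratios(coh, pseudo = 0, log_transform = FALSE)
  r_eps <- group_ratios(coh, pseudo = 1e-10, log_transform = FALSE)
  expect_equal(r_eps$ratio_responder, r0$ratio_responder, tolerance = 1e-9)
  expect_equal(r_eps$ratio_progressor, r0$ratio_progressor, tolerance = 1e-9)
})

test_that("concordance requires inverse pattern, reference match and alpha", {
  screen <- data.frame(mirna_id = c("m1", "m2", "m3", "m4"),
                       fc_wt = 1, sd_wt = 0, fc_null = c(2, 2, 2, 0.5),
                       sd_null = 0.01)
  ratios <- data.frame(
    mirna_id = c("m1", "m2", "m3", "m4"),
    ratio_responder = c(2.0, 2.0, 1.02, 2.0),
    ratio_progressor = c(0.5, 1.6, 0.5, 0.5),
    p_value = c(0.01, 0.01, 0.01, 0.01),
    n_responder = 10, n_progressor = 10, n_untreated = 10,
    undefined_ratio = FALSE)
  ref <- data.frame(mirna_id = c("m1", "m2", "m3", "m4"),
                    direction = c("up", "up", "up", "down"))
  ent <- concordance_screen(ratios, screen, ref)
  expect_equal(ent$concordant, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(ent$direction_responder, c("up", "up", "flat", "up"))

  # significance clause
  ratios$p_value <- 0.2
  expect_false(any(concordance_screen(ratios, screen, ref)$concordant))

  # genotype-derived reference: ATM_null hit calls give m1 "up"
  ratios$p_value <- 0.01
  ent2 <- concordance_screen(ratios, screen, "ATM_null")
  expect_true(ent2$concordant[ent2$mirna_id == "m1"])
  # m4 responder goes up but the ATM_null call is "down": not concordant
  expect_false(ent2$concordant[ent2$mirna_id == "m4"])

  expect_error(concordance_screen(ratios, screen, "ATM_het"),
               "unknown reference")
  ratios2 <- rbind(ratios,
                   data.frame(mirna_id = "m9", ratio_responder = 2,
                              ratio_progressor = 0.5, p_value = 0.01,
                              n_responder = 10, n_progressor = 10,
                              n_untreated = 10, undefined_ratio = FALSE))
  expect_warning(concordance_screen(ratios2, screen, ref), "m9")
})

test_that("miRNAs outside an explicit direction table are never concordant", {
  screen <- data.frame(mirna_id = c("m1", "m2"), fc_wt = 1, sd_wt = 0,
                       fc_null = 2, sd_null = 0.01)
  ratios <- data.frame(mirna_id = c("m1", "m2"), ratio_responder = 2,
                       ratio_progressor = 0.5, p_value = 0.001,
                       n_responder = 10, n_progressor = 10, n_untreated = 10,
                       undefined_ratio = FALSE)
  ref <- data.frame(mirna_id = "m1", direction = "up")
  ent <- concordance_screen(ratios, screen, ref)
  expect_equal(ent$concordant, c(TRUE, FALSE))
  expect_equal(ent$invitro_direction, c("up", "unchanged"))
})

test_that("swapping responder and progressor labels flips the pattern", {
  sim <- simulate_cohort(signature_pattern_config(seed = 21))
  coh <- sim$cohort
  swapped <- coh
  swapped$group[coh$group == "responder"] <- "progressor"
  swapped$group[coh$group == "progressor"] <- "responder"
  r1 <- group_ratios(coh)
  r2 <- group_ratios(swapped)
  expect_equal(r2$ratio_responder, r1$ratio_progressor)
  expect_equal(r2$ratio_progressor, r1$ratio_responder)
  expect_equal(r2$p_value, r1$p_value, tolerance = 1e-12)

  dirs <- signature_directions()
  flipped <- dirs
  flipped$direction <- ifelse(dirs$direction == "up", "down", "up")
  s <- invitro_screen()
  e1 <- concordance_screen(r1, s, dirs)
  e2 <- concordance_screen(r2, s, flipped)
  expect_equal(e2$concordant, e1$concordant)
})

test_that("ATM comparison reports direction and Welch p-value", {
  set.seed(404)
  atm <- list(responder = 1 + rnorm(6, 0, 0.01),
              progressor = 2 + rnorm(6, 0, 0.01),
              untreated = rep(NA_real_, 6))
  coh <- make_cohort(list(responder = list(m1 = runif(6)),
                          progressor = list(m1 = runif(6)),
                          untreated = list(m1 = runif(6))), atm = atm)
  cmp <- atm_group_comparison(coh)
  expect_equal(cmp$direction, -1)
  expect_lt(cmp$p_value, 1e-6)
  expect_equal(cmp$p_value,
               welch_p_oracle(atm$responder, atm$progressor),
               tolerance = 1e-12)

  same <- coh
  same$atm_protein <- 1
  cmp2 <- atm_group_comparison(same)
  expect_equal(cmp2$direction, 0)
  expect_equal(cmp2$p_value, 1)

  sparse <- coh
  sparse$atm_protein[coh$group == "progressor"] <- NA
  expect_error(atm_group_comparison(sparse), "at least 2")
})

test_that("a planted ATM shift is detected in nearly every replicate", {
  hits <- 0L
  for (seed in 1:100) {
    sim <- simulate_cohort(cohort_sim_config(
      seed = seed, n_per_group = 10, mirnas = "m1",
      atm_baseline = 1, atm_progressor_shift = 0.5, atm_noise_sd = 0.2))
    if (atm_group_comparison(sim$cohort)$p_value <= 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 95)
})

test_that("the relative-expression matrix scales by the untreated mean", {
  coh <- make_cohort(list(responder = list(m1 = c(20, 30)),
                          progressor = list(m1 = c(5, 10)),
                          untreated = list(m1 = c(10, 10))))
  mat <- relative_expression_matrix(coh, pseudo = 0)
  expect_equal(dim(mat), c(1, 4))
  expect_equal(unname(mat["m1", ]), c(2, 3, 0.5, 1))
})
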