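test_that("survival components follow the stated exponential laws", {
  sv <- predict_survival(2, human)
  row <- sv[sv$phase == "G1", ]
  # mitotic catastrophe at the checkpoint threshold: e^(-0.014 * 20)
  expect_equal(row$n_mitosis, 20, tolerance = 1e-6)
  expect_equal(row$s_mitotic, exp(-0.28), tolerance = 1e-6)
  # apoptosis on all G1-induced breaks: e^(-0.012 * 70)
  expect_equal(row$s_apoptosis, exp(-0.012 * row$n_g1), tolerance = 1e-9)
  # components multiply exactly
  expect_equal(row$s_total,
               row$s_aberration * row$s_mitotic * row$s_apoptosis)
})

test_that("zero dose survives with certainty in every phase", {
  for (ph in list(human, radiation_phenotype(cycle_phase = "G2"),
                  radiation_phenotype(cycle_phase = "G0"))) {
    dr <- dose_response(c(0), ph)
    expect_equal(dr$s_total, 1)
  }
})

test_that("phase rules gate apoptosis and mitotic catastrophe", {
  g0 <- predict_survival(2, radiation_phenotype(cycle_phase = "G0"))
  expect_equal(g0$s_apoptosis[1], 1)
  expect_equal(g0$s_mitotic[1], 1)

  g2 <- predict_survival(2, radiation_phenotype(cycle_phase = "G2"))
  expect_equal(g2$s_apoptosis[1], 1)
  expect_lt(g2$s_mitotic[1], 1)

  # G1-arrest loss swaps the full apoptosis rate for the residual one
  p53null <- predict_survival(2, radiation_phenotype(
    g1_arrest_competent = FALSE))
  expect_equal(p53null$s_apoptosis[1], exp(-0.0007 * 70.0036),
               tolerance = 1e-6)
  expect_gt(p53null$s_total[1], predict_survival(2, human)$s_total[1])
})

test_that("asynchronous survival is the convex phase mixture", {
  async <- radiation_phenotype(cycle_phase = "asynchronous",
                               phase_fractions = c(G1 = 0.5, G2 = 0.5))
  sv <- predict_survival(2, async)
  parts <- sv[sv$phase != "combined", ]
  comb <- sv[sv$phase == "combined", ]
  expect_equal(comb$s_total, sum(0.5 * parts$s_total), tolerance = 1e-12)
  expect_true(comb$s_total >= min(parts$s_total) - 1e-12 &&
                comb$s_total <= max(parts$s_total) + 1e-12)
})

test_that("dose-response is monotone and repair defects lower it everywhere", {
  doses <- c(0, 1, 2, 4, 8)
  dr <- dose_response(doses, human)
  expect_true(all(diff(dr$s_total) < 0))
  drn <- dose_response(doses, radiation_phenotype(nhej_competent = FALSE))
  expect_true(all(drn$s_total[-1] < dr$s_total[-1]))
})

test_that("MID integrates the survival curve and matches the LQ closed form", {
  expect_equal(mid_lq(1, 0), 1)
  # erfc closed form against adaptive quadrature on an LQ curve
  alpha <- 0.5; beta <- 0.05
  lq_curve <- structure(
    tibble::tibble(dose_gy = c(0, 5), s_total = exp(-alpha * c(0, 5) -
                                                      beta * c(0, 25))),
    class = c("dose_response", "tbl_df", "tbl", "data.frame"),
    survival_fn = function(d) exp(-alpha * d - beta * d^2))
  expect_equal(mid(lq_curve), mid_lq(alpha, beta), tolerance = 1e-6)
  # Simpson mode agrees to its stated accuracy
  expect_equal(mid(lq_curve, n_grid = 48), mid_lq(alpha, beta),
               tolerance = 1e-3)
  # identical curves give RBE exactly 1
  expect_equal(rbe_mid(lq_curve, lq_curve), 1)
})

test_that("MID falls when any lethality rate rises", {
  doses <- c(0, 1, 2, 4, 6)
  base <- mid(dose_response(doses, human), n_grid = 16)
  hot_phi <- mid(dose_response(doses, human,
                               s_params = survival_parameters(phi = 0.05)),
                 n_grid = 16)
  hot_psi <- mid(dose_response(doses, human,
                               s_params = survival_parameters(
                                 psi_full = 0.03)), n_grid = 16)
  wide_sigma <- mid(dose_response(doses, human,
                                  params = repair_parameters(sigma = 0.1)),
                    n_grid = 16)
  expect_lt(hot_phi, base)
  expect_lt(hot_psi, base)
  expect_lt(wide_sigma, base)
})

test_that("track-number averaging is bypassed below the 0.5 DSB/track threshold", {
  prof_low <- synthetic_track_profile(3)  # ~0.45 DSB per track
  expect_lt(dsbs_per_track(prof_low, geo), 0.5)
  s_avg <- predict_survival(2, human, profile = prof_low,
                            track_average = TRUE)
  s_off <- predict_survival(2, human, profile = prof_low,
                            track_average = FALSE)
  expect_equal(s_avg$s_total, s_off$s_total, tolerance = 1e-12)
})

test_that("Poisson track-number fluctuations spare survival at high LET", {
  prof <- synthetic_track_profile(200)
  s_avg <- predict_survival(2, human, profile = prof,
                            track_average = TRUE)$s_total[1]
  s_fix <- predict_survival(2, human, profile = prof,
                            track_average = FALSE)$s_total[1]
  expect_gt(s_avg, s_fix)  # averaging a convex response helps survival
})

test_that("LQ summary fit recovers parameters from an LQ-shaped curve", {
  alpha <- 0.3; beta <- 0.04
  doses <- c(0, 1, 2, 4, 6, 8)
  fake <- structure(
    tibble::tibble(dose_gy = doses,
                   s_total = exp(-alpha * doses - beta * doses^2)),
    class = c("dose_response", "tbl_df", "tbl", "data.frame"))
  fit <- fit_lq(fake)
  expect_equal(fit$alpha, alpha, tolerance = 1e-8)
  expect_equal(fit$beta, beta, tolerance = 1e-8)
})

test_that("tidy and glance expose dose-response and event-log summaries", {
  dr <- dose_response(c(0, 2, 4), human)
  td <- tidy(dr)
  expect_true(all(c("dose_gy", "s_total") %in% names(td)))
  gl <- glance(dr)
  expect_true(gl$mid_gy > 0)

  asg <- assign_pathways(human, rp, "G1")
  log <- mc_repair(generate_uniform(1, human, geo, rp, seed = 2), asg, rp,
                   seed = 3)
  expect_equal(glance(log)$n_events, nrow(tidy(log)))
})

test_that("autoplot methods return ggplot objects", {
  kin <- repair_kinetics(acute_exposure(1), human, geo, rp,
                         times = c(0, 1, 4, 24))
  expect_s3_class(autoplot(kin), "ggplot")
  dr <- dose_response(c(0, 2), human)
  expect_s3_class(autoplot(dr), "ggplot")
  pat <- generate_uniform(1, human, geo, rp, seed = 5)
  expect_s3_class(autoplot(pat), "ggplot")
})
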