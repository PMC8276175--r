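test_that("phenotype construction validates its invariants", {
  expect_s3_class(radiation_phenotype(), "radiation_phenotype")
  expect_error(radiation_phenotype(genome_size = -1), "genome_size")
  expect_error(radiation_phenotype(long_term_failure_fraction = 1.2),
               "long_term_failure")
  expect_error(radiation_phenotype(cycle_phase = "asynchronous",
                                   phase_fractions = c(G1 = 0.6, S = 0.3)),
               "sum to 1")
  expect_error(radiation_phenotype(cycle_phase = "G1",
                                   phase_fractions = c(G1 = 1)),
               "asynchronous")
})

test_that("resolve_phases returns single phases and asynchronous mixtures", {
  expect_equal(resolve_phases(human),
               tibble::tibble(phase = "G1", weight = 1))
  async <- radiation_phenotype(cycle_phase = "asynchronous",
                               phase_fractions = c(G1 = 0.6, S = 0.3,
                                                   G2 = 0.1))
  ph <- resolve_phases(async)
  expect_equal(ph$phase, c("G1", "S", "G2"))
  expect_equal(sum(ph$weight), 1)
  # default mixture when no fractions given
  def <- resolve_phases(radiation_phenotype(cycle_phase = "asynchronous"))
  expect_equal(sum(def$weight), 1)
})

test_that("pathway assignment reproduces the stated routing rules", {
  # repair competent G1: p_f = 1 - p_c, p_s = p_c
  a <- assign_pathways(human, rp, "G1")
  expect_equal(unname(a$p), c(0.57, 0.43, 0), tolerance = 1e-12)
  expect_equal(a$p_unrepaired, 0)
  expect_identical(a$slow_route, "NHEJ")

  # HR-deficient G2: slow keeps (1 - p_fail), MMEJ takes p_fail
  b <- assign_pathways(radiation_phenotype(hr_competent = FALSE), rp, "G2")
  expect_equal(unname(b$p), c(0.57, 0.43 * 0.26, 0.43 * 0.74),
               tolerance = 1e-12)

  # competent G2 routes complex breaks through HR (fully faithful slow)
  g2 <- assign_pathways(human, rp, "G2")
  expect_identical(g2$slow_route, "HR")
  expect_equal(unname(g2$mu[["slow"]]), 1)
  expect_false(g2$binary_eligible[["slow"]])

  # no complex breaks: everything is fast regardless of HR status
  p0 <- repair_parameters(p_complex = 0)
  c0 <- assign_pathways(radiation_phenotype(hr_competent = FALSE), p0, "G2")
  expect_equal(unname(c0$p), c(1, 0, 0))

  expect_error(assign_pathways(human, rp, "M"), "phase")
})

test_that("assignment probabilities always close to 1 with the unrepaired pool", {
  phenos <- list(
    human,
    radiation_phenotype(nhej_competent = FALSE),
    radiation_phenotype(hr_competent = FALSE),
    radiation_phenotype(nhej_competent = FALSE, hr_competent = FALSE),
    radiation_phenotype(long_term_failure_fraction = 0.22)
  )
  for (ph in phenos) {
    for (phase in c("G0", "G1", "S", "G2")) {
      a <- assign_pathways(ph, rp, phase)
      expect_equal(sum(a$p) + a$p_unrepaired, 1, tolerance = 1e-12)
      expect_true(all(a$p >= 0 & a$p <= 1))
    }
  }
})

test_that("p_fail = 0 restores the competent assignment for unaffected classes", {
  p0 <- repair_parameters(p_fail = 0)
  def <- assign_pathways(radiation_phenotype(hr_competent = FALSE), p0, "G2")
  comp <- assign_pathways(human, p0, "G2")
  expect_equal(def$p, comp$p, tolerance = 1e-12)
})

test_that("routing override table is honoured and validated", {
  ov <- list(simple = c(fast = 0.5, slow = 0.5, mmej = 0, fail = 0))
  a <- assign_pathways(human, rp, "G1", override = ov)
  expect_equal(unname(a$p[["fast"]]), 0.57 / 0.57 * 0.5 * (1 - rp$p_complex),
               tolerance = 1e-12)
  expect_error(assign_pathways(human, rp, "G1",
                               override = list(simple = c(fast = 0.7))),
               "sum to 1|named")
})

test_that("default parameter objects carry the published best-fit values", {
  p <- repair_parameters()
  expect_identical(
    unlist(p[c("sigma", "mu_nhej", "mu_mmej", "p_mut", "p_complex",
               "p_fail", "lambda_f", "lambda_s", "lambda_m", "nu_f",
               "nu_s")]),
    c(sigma = 0.0418, mu_nhej = 0.985, mu_mmej = 0.44, p_mut = 0.046,
      p_complex = 0.43, p_fail = 0.74, lambda_f = 2.1, lambda_s = 0.26,
      lambda_m = 0.0085, nu_f = 8.1, nu_s = 0.41))
  s <- survival_parameters()
  expect_identical(unlist(s[c("phi", "psi_full", "psi_base")]),
                   c(phi = 0.014, psi_full = 0.012, psi_base = 0.0007))
  expect_equal(s$checkpoint_threshold, 20)
  expect_equal(s$large_deletion_threshold, 3)
  expect_error(survival_parameters(psi_base = 0.02), "psi_base")
})

test_that("nucleus geometry is calibrated to the energy-per-DSB constant", {
  g <- nucleus_geometry()
  expect_equal(round(g$radius, 2), 4.23)
  # one Gy deposits exactly the energy for the expected DSB count
  expect_equal(medras:::KEV_PER_UM3_PER_GY * g$volume / g$e_dsb,
               expected_dsb_count(1, g$genome_size, g$dsb_yield),
               tolerance = 1e-12)
  expect_lt(chromosome_radius(g, 46), g$radius)
  expect_equal(chromosome_radius(g, 1), g$radius)
})

test_that("dose protocols validate segments and track totals", {
  p <- fractionated_exposure(2, n_fractions = 3, interval = 24)
  expect_equal(total_dose(p), 6)
  expect_error(dose_protocol(tibble::tibble(start = c(0, 1),
                                            duration = c(2, 2),
                                            dose = c(1, 1))),
               "overlap")
  cont <- continuous_exposure(2, dose_rate = 0.5)
  expect_equal(dose_rate_at(cont, c(0, 3.9, 4.1)), c(0.5, 0.5, 0))
  expect_equal(total_dose(cont), 2)
})
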