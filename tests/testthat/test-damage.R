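test_that("expected DSB count follows the linear yield relation", {
  expect_equal(expected_dsb_count(1, 6100, 5.738), 35.0018)
  expect_equal(expected_dsb_count(0, 6100), 0)
  # linear in dose x genome
  expect_equal(expected_dsb_count(2, 3050, 5.738),
               expected_dsb_count(1, 6100, 5.738))
  expect_error(expected_dsb_count(-1), "non-negative")
})

test_that("uniform generator has Poisson counts and uniform-in-sphere positions", {
  expect_equal(nrow(generate_uniform(0, human, geo, rp, seed = 1)), 0)

  counts <- vapply(1:400, function(i) {
    nrow(generate_uniform(1, human, geo, rp, seed = i))
  }, numeric(1))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 35.0018), 3 * se)

  pat <- generate_uniform(0, human, geo, rp, seed = 7,
                          n_breaks = 4000)
  r <- sqrt(pat$x^2 + pat$y^2 + pat$z^2)
  expect_true(all(r <= geo$radius))
  # radial CDF of uniform points in a sphere is (r/R)^3
  ks <- suppressWarnings(ks.test(r, function(q) (q / geo$radius)^3))
  expect_gt(ks$p.value, 0.01)
  # complexity flags are Bernoulli(p_complex)
  se_c <- sqrt(rp$p_complex * (1 - rp$p_complex) / nrow(pat))
  expect_lt(abs(mean(pat$complex) - rp$p_complex), 3 * se_c)
})

test_that("dsbs_per_track sums bin energies over the chord", {
  prof <- track_profile(r_inner = c(0, 0.01, 0.1),
                        r_outer = c(0.01, 0.1, 1),
                        energy = c(5, 3, 2))
  expect_equal(dsbs_per_track(prof, geo, chord_length = 8.46),
               10 * 8.46 / 56.5, tolerance = 1e-12)
  # linearity in bin energy
  prof2 <- track_profile(prof$r_inner, prof$r_outer, 2 * prof$energy)
  expect_equal(dsbs_per_track(prof2, geo), 2 * dsbs_per_track(prof, geo))
  # E_DSB -> infinity kills the yield (fixed chord: the default radius
  # would grow with the calibration energy)
  g_inf <- nucleus_geometry(e_dsb = 1e12)
  expect_lt(dsbs_per_track(prof, g_inf, chord_length = 8.46), 1e-9)
  expect_error(track_profile(numeric(), numeric(), numeric()), "empty")
})

test_that("track generator conserves the DSB yield at equal dose", {
  prof <- synthetic_track_profile(30)
  counts <- vapply(1:300, function(i) {
    nrow(generate_track_pattern(1, prof, human, geo, rp, seed = i))
  }, numeric(1))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 35.0018), 3 * se)

  expect_equal(nrow(generate_track_pattern(0, prof, human, geo, rp,
                                           seed = 1)), 0)

  # narrow profile: all breaks within the stated radius of the track axis
  narrow <- track_profile(c(0), c(0.01), c(50))
  pat <- generate_track_pattern(2, narrow, human, geo, rp, seed = 3)
  expect_true(all(sqrt(pat$x^2 + pat$y^2) <= 0.01 + 1e-12))
  expect_true(all(pat$x^2 + pat$y^2 + pat$z^2 <= geo$radius^2 + 1e-9))

  # profile entirely outside the nucleus is degenerate
  outside <- track_profile(c(10), c(20), c(50))
  expect_error(generate_track_pattern(1, outside, human, geo, rp, seed = 1),
               "degenerate|no energy")
})

test_that("clustered patterns have much shorter intra-track pair distances", {
  prof <- synthetic_track_profile(50)
  clus <- generate_fixture_suite("clustered-track", dose = 2, seed = 5)
  unif <- generate_fixture_suite("uniform", dose = 2, seed = 5)
  pair_d <- function(p) {
    if (nrow(p) < 2) return(NA_real_)
    mean(dist(as.matrix(p[, c("x", "y", "z")])))
  }
  intra_d <- clus |>
    dplyr::group_by(.data$track_id) |>
    dplyr::filter(dplyr::n() > 1) |>
    dplyr::group_map(~ as.numeric(dist(as.matrix(.x[, c("x", "y", "z")])))) |>
    unlist()
  unif_d <- as.numeric(dist(as.matrix(unif[, c("x", "y", "z")])))
  # tracks compress the radial coordinate: intra-track pairs are shorter
  # on average and vastly enriched in close (< 2 sigma) encounters
  expect_lt(mean(intra_d), 0.8 * mean(unif_d))
  close_intra <- mean(intra_d < 2 * sigma_abs)
  close_unif <- mean(unif_d < 2 * sigma_abs)
  expect_gt(close_intra, 10 * close_unif)
})

test_that("fixture generation is deterministic for a fixed seed", {
  a <- generate_fixture_suite("uniform", dose = 2, seed = 11)
  b <- generate_fixture_suite("uniform", dose = 2, seed = 11)
  expect_identical(as.data.frame(a), as.data.frame(b))

  d1 <- generate_fixture_suite("toy-sdd", dose = 1, seed = 3,
                               dir = withr::local_tempdir())
  d2 <- generate_fixture_suite("toy-sdd", dose = 1, seed = 3,
                               dir = withr::local_tempdir())
  expect_identical(readLines(d1$path), readLines(d2$path))
})

test_that("schedule_inductions spreads breaks over the protocol in dose proportion", {
  pat <- generate_uniform(0, human, geo, rp, seed = 2, n_breaks = 2000)
  proto <- dose_protocol(tibble::tibble(start = c(0, 10),
                                        duration = c(2, 0),
                                        dose = c(1, 3)))
  out <- schedule_inductions(pat, proto, seed = 4)
  expect_true(all(out$induction_time <= 12))
  frac_late <- mean(out$induction_time == 10)
  expect_lt(abs(frac_late - 0.75), 3 * sqrt(0.75 * 0.25 / 2000))
  expect_true(!is.unsorted(out$induction_time))
})
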