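test_that("zeta is a normalized Gaussian interaction", {
  expect_equal(zeta(0, 0.2), 1)
  expect_equal(zeta(0.2 * sqrt(2 * log(2)), 0.2), 0.5, tolerance = 1e-12)
  expect_lt(zeta(5, 0.2), 1e-100)
  expect_error(zeta(1, 0), "sigma")
  expect_error(zeta(-1, 0.2), "non-negative")
})

test_that("theta has the right limits and matches quadrature everywhere", {
  expect_equal(theta(4.23, 1e6), 1, tolerance = 1e-6)
  expect_lt(theta(4.23, 1e-6), 1e-12)
  expect_equal(theta(1, 0.3, Inf), theta(1, 0.3, 2))  # truncation at 2R

  quad <- function(R, s, d) {
    f <- function(r) exp(-r^2 / (2 * s^2)) *
      (3 * r^2 / R^3 - 9 * r^3 / (4 * R^4) + 3 * r^5 / (16 * R^6))
    integrate(f, 0, min(d, 2 * R), rel.tol = 1e-12)$value
  }
  for (case in list(c(4.23, 0.177, Inf), c(4.23, 0.177, 0.3),
                    c(1.18, 0.177, Inf), c(1, 0.5, 0.7), c(2, 25, Inf))) {
    expect_equal(theta(case[1], case[2], case[3]),
                 quad(case[1], case[2], case[3]),
                 tolerance = 1e-9)
  }
})

test_that("theta matches a Monte-Carlo pair-sampling estimate", {
  # moderate n here; the full 1e7-pair check runs in the acceptance suite
  set.seed(99)
  n <- 4e5
  draw <- function() {
    m <- matrix(runif(3 * 2 * n, -geo$radius, geo$radius), ncol = 3)
    m[rowSums(m^2) < geo$radius^2, , drop = FALSE]
  }
  a <- draw(); b <- draw()
  k <- min(nrow(a), nrow(b))
  zz <- exp(-rowSums((a[1:k, ] - b[1:k, ])^2) / (2 * sigma_abs^2))
  se <- sd(zz) / sqrt(k)
  expect_lt(abs(mean(zz) - theta(geo$radius, sigma_abs)), 3 * se)
})

test_that("eta_prime agrees with brute-force double summation over patterns", {
  # eta' (N-1) must reproduce the mean per-break misrepair rate
  # 2 sum_{j != i} zeta(r_ij) over uniform patterns of N = 100 breaks
  n <- 100
  etas <- vapply(1:200, function(i) {
    pat <- generate_uniform(0, human, geo, rp, seed = 500 + i,
                            n_breaks = n)
    z <- exp(-as.matrix(dist(as.matrix(pat[, c("x", "y", "z")])))^2 /
               (2 * sigma_abs^2))
    diag(z) <- 0
    mean(2 * colSums(z))
  }, numeric(1))
  se <- sd(etas) / sqrt(length(etas))
  expect_lt(abs(mean(etas) - eta_prime(geo, sigma_abs) * (n - 1)), 3 * se)

  # scale invariance and small-range limit
  expect_equal(eta_prime(nucleus_geometry(radius = 2), 0.1),
               eta_prime(nucleus_geometry(radius = 4), 0.2),
               tolerance = 1e-9)
  expect_lt(eta_prime(geo, 1e-8), 1e-20)
})

test_that("complete-repair correct probability matches its closed form", {
  expect_equal(p_correct_complete(0.5, 0), 1)
  expect_equal(p_correct_complete(1e-12, 100), 1, tolerance = 1e-9)
  # eta' N = 1 evaluates to pi / (3 sqrt(3))
  expect_equal(p_correct_complete(0.01, 100), pi / (3 * sqrt(3)),
               tolerance = 1e-12)
  # monotone decreasing in eta' N
  x <- seq(0, 10, by = 0.1)
  p <- p_correct_complete(x, 1)
  expect_true(all(diff(p) <= 0))
})

test_that("partial-repair form matches quadrature of the instantaneous rate", {
  quad <- function(a, n0, n1) {
    integrate(function(n) 1 / (1 + a * n + (a * n)^2), n1, n0,
              rel.tol = 1e-12)$value / (n0 - n1)
  }
  for (case in list(c(0.01, 50, 10), c(0.0005, 2800, 100),
                    c(0.05, 40, 39), c(0.3, 10, 0))) {
    expect_equal(p_correct_partial(case[1], case[2], case[3]),
                 quad(case[1], case[2], case[3]), tolerance = 1e-8)
  }
  # complete-repair reduction and the degenerate-interval limit
  expect_equal(p_correct_partial(0.02, 50, 0), p_correct_complete(0.02, 50),
               tolerance = 1e-14)
  expect_equal(p_correct_partial(0.01, 100, 100),
               1 / (1 + 1 + 1), tolerance = 1e-12)
  expect_error(p_correct_partial(0.01, 10, 20), "exceed")
})

test_that("acute misrepair equals the complete-repair closed form", {
  ep <- eta_prime(geo, sigma_abs)
  for (d in c(0.5, 10, 80)) {
    mis <- misrepair_analytic(acute_exposure(d), human, geo, rp)
    n0 <- expected_dsb_count(d)
    expect_equal(mis$n_mis_binary, n0 * (1 - p_correct_complete(ep, n0)),
                 tolerance = 1e-9)
    expect_equal(mis$n_correct + mis$n_mis, mis$n_repaired,
                 tolerance = 1e-9)
    expect_gte(mis$p_correct, 0)
  }
})

test_that("misrepair per unit dose collapses to the single-hit floor at low dose rate", {
  acute <- misrepair_analytic(acute_exposure(2), human, geo, rp)
  slow <- misrepair_analytic(continuous_exposure(2, dose_rate = 0.02),
                             human, geo, rp)
  expect_lt(slow$n_mis_binary, acute$n_mis_binary)
  expect_lt(slow$n_mis_binary, 0.2 * acute$n_mis_binary)
  # process (single-hit) misrepair is dose-rate independent
  expect_equal(slow$n_mis_process, acute$n_mis_process, tolerance = 0.02)
})

test_that("well-separated fractions misrepair like independent exposures", {
  two <- misrepair_analytic(fractionated_exposure(1, 2, interval = 300),
                            human, geo, rp)
  one <- misrepair_analytic(acute_exposure(1), human, geo, rp)
  expect_equal(two$n_mis_binary, 2 * one$n_mis_binary, tolerance = 0.02)
})

test_that("misrepair counts stay within their logical bounds across phenotypes", {
  for (ph in list(human, radiation_phenotype(nhej_competent = FALSE),
                  radiation_phenotype(long_term_failure_fraction = 0.22))) {
    mis <- misrepair_analytic(acute_exposure(4), ph, geo, rp)
    expect_gte(mis$n_mis, 0)
    expect_lte(mis$n_mis, mis$n_repaired + 1e-9)
    expect_true(mis$p_correct >= 0 && mis$p_correct <= 1)
    expect_equal(mis$n_repaired + mis$n_unrepaired, mis$n_induced,
                 tolerance = 1e-6)
  }
})

test_that("intra-track interaction raises misrepair for clustered damage", {
  prof <- synthetic_track_profile(80)
  et <- eta_track(prof, geo, sigma_abs, seed = 1)
  expect_gt(et, 10 * eta_prime(geo, sigma_abs))
  with_track <- misrepair_analytic(acute_exposure(1), human, geo, rp,
                                   eta_track_value = et)
  without <- misrepair_analytic(acute_exposure(1), human, geo, rp)
  expect_gt(with_track$n_mis_binary, without$n_mis_binary)

  # profiles with ~no intra-track partners contribute nothing
  thin <- synthetic_track_profile(0.1)
  expect_warning(et0 <- eta_track(thin, nucleus_geometry(e_dsb = 1e9),
                                  sigma_abs, seed = 1),
                 "no intra-track")
  expect_equal(et0, 0)
})
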