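test_that("intra-chromosome probability has the right structure and limits", {
  # single chromosome: everything is intra
  expect_equal(p_intra(geo, sigma_abs, 1), 1)
  pi_h <- p_intra(geo, sigma_abs, 46)
  expect_gt(pi_h, 0)
  expect_lte(pi_h, 1)
  # very diffuse interaction: partner counting takes over (1/n_c)
  expect_equal(p_intra(geo, 1e5, 46), 1 / 46, tolerance = 1e-4)
  # tighter interaction ranges concentrate misrepair within a chromosome
  expect_gt(p_intra(geo, 0.05, 46), p_intra(geo, 1, 46))
})

test_that("analytic p_intra matches a territory-resolved simulation", {
  # breaks carry the chromosome of their territory; the intra fraction of
  # zeta-weighted partner mass approximates the sphere-territory model at
  # the ~10% level (compact Voronoi cells are not perfect spheres)
  set.seed(1234)
  fr <- vapply(1:40, function(i) {
    pat <- generate_uniform(0, human, geo, rp, seed = 1800 + i,
                            n_breaks = 300)
    z <- exp(-as.matrix(dist(as.matrix(pat[, c("x", "y", "z")])))^2 /
               (2 * sigma_abs^2))
    diag(z) <- 0
    same <- outer(pat$chromosome, pat$chromosome, "==")
    sum(z[same]) / sum(z)
  }, numeric(1))
  an <- p_intra(geo, sigma_abs, 46)
  expect_lt(abs(mean(fr) - an), 0.1 * an)
})

test_that("aberration identities hold exactly for expected counts", {
  ab <- classify_misrepair(2, geo, sigma_abs, human, sp)
  expect_equal(ab$n_dicentric, 0.5 * 2 * (1 - ab$p_intra))
  expect_equal(ab$n_deletion, 0.5 * 2 * ab$p_intra)
  expect_equal(ab$n_dicentric + ab$n_deletion + ab$n_symmetric, 2)
  expect_lte(ab$n_deletion_large, ab$n_deletion)
  expect_lte(ab$n_interarm, ab$n_deletion + 1e-12)

  z <- classify_misrepair(0, geo, sigma_abs, human, sp)
  expect_equal(z$n_dicentric + z$n_deletion + z$n_interarm +
                 z$n_symmetric, 0)
})

test_that("deletion-size distribution is a valid CDF tied to the distance map", {
  d <- c(0, 0.1, 0.5, 1, 3, 10, 100, 1e5)
  cdf <- deletion_size_cdf(d, geo, sigma_abs, 46, 6100)
  expect_equal(cdf[1], 0)
  expect_true(all(diff(cdf) >= -1e-12))
  expect_equal(cdf[length(cdf)], 1, tolerance = 1e-9)
  expect_true(all(cdf >= 0 & cdf <= 1 + 1e-12))
})

test_that("deletion sizes from the MC engine follow the analytic CDF", {
  asg <- assign_pathways(human, rp, "G1")
  spans <- unlist(lapply(1:40, function(i) {
    pat <- generate_uniform(10, human, geo, rp, seed = 2500 + i)
    log <- mc_repair(pat, asg, rp, seed = 2600 + i)
    ab <- classify_events(log, geo, human, sp, seed = 2700 + i)
    ev <- attr(ab, "events")
    ev$genomic_span_mapped[ev$type == "deletion"]
  }))
  expect_gt(length(spans), 100)
  # Late orphan pairings (ends whose partners were consumed earlier) join
  # over systematically larger distances than the zeta-weighted analytic
  # density allows, so the event engine's spans sit stochastically above
  # the closed-form CDF; the two agree at the 0.1-0.2 level on the
  # decision-relevant MBP scales.
  emp <- ecdf(spans)
  for (q in c(1, 3, 10, 30)) {
    an <- deletion_size_cdf(q, geo, sigma_abs, 46, 6100)
    expect_lte(emp(q), an + 0.05)   # spans are larger, not smaller
    expect_gte(emp(q), an - 0.2)
  }
  m_an <- uniroot(function(d) deletion_size_cdf(d, geo, sigma_abs, 46,
                                                6100) - 0.5,
                  c(1e-6, 1e4))$root
  expect_lt(median(spans) / m_an, 2)
  expect_gt(median(spans) / m_an, 1)
})

test_that("event classification applies the symmetry coin and intra split", {
  # forced single inter-chromosome misrepair: dicentric half the time
  two <- fixed_pattern(rbind(c(0, 0, 0), c(0.05, 0, 0)),
                       chromosome = c(1, 2))
  asg <- assign_pathways(human, rp, "G1")
  dics <- vapply(1:2000, function(i) {
    log <- mc_repair(two, asg, rp, seed = 3200 + i)
    ab <- classify_events(log, geo, human, sp, seed = 4200 + i)
    c(ab$n_dicentric, ab$n_mis)
  }, numeric(2))
  n_mis_events <- sum(dics[2, ])
  frac_dic <- sum(dics[1, ]) / n_mis_events
  se <- sqrt(0.25 / n_mis_events)
  expect_lt(abs(frac_dic - 0.5), 3 * se)

  # all-correct log classifies to zeros
  one <- fixed_pattern(c(0, 0, 0))
  log1 <- mc_repair(one, asg, rp, seed = 1)
  ab1 <- classify_events(log1, geo, human, sp, seed = 2)
  expect_equal(ab1$n_mis, 0)
  expect_equal(ab1$n_dicentric + ab1$n_deletion + ab1$n_symmetric, 0)
})

test_that("MC intra-chromosome misrepair fraction approximates the analytic value", {
  asg <- assign_pathways(human, rp, "G1")
  fr <- unlist(lapply(1:25, function(i) {
    pat <- generate_uniform(20, human, geo, rp, seed = 6100 + i)
    log <- mc_repair(pat, asg, rp, seed = 6200 + i)
    mis <- log[!log$same_dsb, ]
    mean(!mis$inter_chromosome)
  }))
  an <- p_intra(geo, sigma_abs, 46)
  expect_lt(abs(mean(fr) - an), 0.12 * an)
})

test_that("mutation yields decompose into structural and point parts", {
  mis <- misrepair_analytic(acute_exposure(2), human, geo, rp)
  mut <- mutation_rate(0.05, mis, geo, human, rp)
  expect_equal(mut$total, mut$structural + mut$point)
  expect_gt(mut$total, 0)

  # vanishing gene still catches structural events spanning it
  m0 <- mutation_rate(0, mis, geo, human, rp)
  expect_equal(m0$point, 0)
  expect_lt(m0$total, mut$total)

  # no misrepair and no point mutability: nothing left
  p0 <- repair_parameters(p_mut = 0, mu_nhej = 1, mu_mmej = 1,
                          sigma = 1e-9)
  mis0 <- misrepair_analytic(acute_exposure(2), human, geo, p0)
  mut0 <- mutation_rate(0.05, mis0, geo, human, p0)
  expect_lt(mut0$total, 1e-8)

  expect_error(mutation_rate(500, mis, geo, human, rp), "chromosome")
})

test_that("point-mutation share of the total falls with dose", {
  share <- vapply(c(1, 10), function(d) {
    mis <- misrepair_analytic(acute_exposure(d), human, geo, rp)
    mut <- mutation_rate(0.05, mis, geo, human, rp)
    mut$point / mut$total
  }, numeric(1))
  expect_lt(share[2], share[1])
})
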