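#' Gaussian proximity interaction between break ends
#'
#' The relative rate at which two free break ends separated by `r` are
#' joined is `exp(-r^2 / (2 sigma^2))`, normalized so that the two ends of
#' a single DSB (r = 0) interact at unit rate.
#'
#' @param r Separation in um (vector).
#' @param sigma_abs Rejoining range in um (sigma fraction times the
#'   nucleus radius).
#' @return Relative interaction rate in `[0, 1]`.
#' @examples
#' zeta(0, 0.18)                      # 1
#' zeta(0.18 * sqrt(2 * log(2)), 0.18)  # 0.5
#' @export
zeta <- function(r, sigma_abs) {
  if (sigma_abs <= 0) abort("`sigma_abs` must be > 0.")
  if (any(r < 0)) abort("`r` must be non-negative.")
  exp(-r^2 / (2 * sigma_abs^2))
}

#' Mean pairwise rejoining rate in a sphere
#'
#' `theta(R, sigma)` is the mean of [zeta()] over the distance between two
#' independent uniform points in a sphere of radius `R` — the building
#' block of the analytic misrepair model.  The generalized form truncates
#' the average at separations below `r_max`, which yields the deletion
#' size distribution.  Closed forms are used (derived from the uniform
#' pair-distance density `3r^2/R^3 - 9r^3/(4R^4) + 3r^5/(16R^6)` on
#' `[0, 2R]`); for very diffuse interaction (`sigma > 10 R`) the
#' expression is evaluated by quadrature to avoid catastrophic
#' cancellation.
#'
#' @param radius Sphere radius `R` in um (nucleus or chromosome
#'   territory).
#' @param sigma_abs Rejoining range in um.
#' @param r_max Truncation distance in um (`Inf` for the plain mean).
#' @return Dimensionless mean rate in `[0, 1]`; `theta -> 1` as
#'   `sigma -> Inf` and `-> 0` as `sigma -> 0`.
#' @examples
#' theta(4.23, 0.0418 * 4.23)
#' @export
theta <- function(radius, sigma_abs, r_max = Inf) {
  check_number(radius, "radius", min = 1e-12)
  check_number(sigma_abs, "sigma_abs", min = 1e-300)
  if (r_max < 0) abort("`r_max` must be non-negative.")
  d <- min(r_max, 2 * radius)
  if (d == 0) return(0)
  R <- radius
  s <- sigma_abs
  if (s > 10 * R) {
    # cancellation kills the closed form when zeta is nearly flat
    f <- function(r) exp(-r^2 / (2 * s^2)) *
      (3 * r^2 / R^3 - 9 * r^3 / (4 * R^4) + 3 * r^5 / (16 * R^6))
    return(integrate(f, 0, d, rel.tol = 1e-12)$value)
  }
  E <- exp(-d^2 / (2 * s^2))
  E * (-3 * d * s^2 / R^3 + 9 * d^2 * s^2 / (4 * R^4) +
         9 * s^4 / (2 * R^4) - 3 * d^4 * s^2 / (16 * R^6) -
         3 * d^2 * s^4 / (4 * R^6) - 3 * s^6 / (2 * R^6)) +
    3 * sqrt(2 * pi) * s^3 / (2 * R^3) * erf(d / (sqrt(2) * s)) -
    9 * s^4 / (2 * R^4) + 3 * s^6 / (2 * R^6)
}

#' Mean per-break interaction rate in a uniform sphere
#'
#' `eta_prime` is the average total misrepair rate contributed per other
#' break: the per-break rate in a pattern of `N` uniform breaks is
#' `eta = eta_prime * N`, with `eta_prime = 2 theta(R, sigma)` (the factor
#' 2 counts the two free ends of each partner break).
#'
#' @param geometry A [nucleus_geometry()].
#' @param sigma_abs Rejoining range in um; defaults to
#'   `sigma * R` from `params`.
#' @param params A [repair_parameters()] (used only for the default
#'   `sigma_abs`).
#' @return `eta_prime` (dimensionless).
#' @export
eta_prime <- function(geometry, sigma_abs = NULL, params = repair_parameters()) {
  stopifnot(inherits(geometry, "nucleus_geometry"))
  sigma_abs <- sigma_abs %||% (params$sigma * geometry$radius)
  2 * theta(geometry$radius, sigma_abs)
}

#' Probability of correct repair for complete repair of an acute exposure
#'
#' Closed form for the fraction of breaks correctly rejoined when `n0`
#' simultaneously present breaks repair to completion, with mean pairwise
#' interaction `eta_prime`:
#' `P = 2/(sqrt(3) x) atan(sqrt(3) x / (2 + x))` with `x = eta_prime n0`.
#'
#' @param eta_prime Mean pairwise interaction rate per break (possibly
#'   including an intra-track component).
#' @param n0 Initial break count.
#' @return Correct-repair probability (1 at `n0 = 0` by continuity).
#' @examples
#' p_correct_complete(1 / 35, 35)  # eta'N = 1: pi/(3 sqrt(3)) = 0.6046
#' @export
p_correct_complete <- function(eta_prime, n0) {
  if (any(n0 < 0)) abort("`n0` must be non-negative.")
  x <- eta_prime * n0
  out <- ifelse(x < 1e-8,
                1 - x / 2,  # Taylor limit, exact to O(x^2)
                2 / (sqrt(3) * x) * atan(sqrt(3) * x / (2 + x)))
  pmin(1, out)
}

#' Probability of correct repair over a partial repair interval
#'
#' The general form for the correct-repair probability while the break
#' population falls from `n0` to `n1` (complete repair is `n1 = 0`).  It
#' is the exact mean of the instantaneous correct probability
#' `1 / (1 + eta + eta^2)` over the interval (the quadratic term is the
#' first-order contribution of partner ends orphaned by earlier
#' misrepair):
#' `P = 2 / (sqrt(3) a dN) * [atan((2 a n0 + 1)/sqrt(3)) -
#'      atan((2 a n1 + 1)/sqrt(3))]` with `a = eta_prime`.
#'
#' @inheritParams p_correct_complete
#' @param n1 Final break count (`0 <= n1 <= n0`).
#' @return Correct-repair probability over the interval.
#' @export
p_correct_partial <- function(eta_prime, n0, n1) {
  if (any(n1 > n0)) abort("`n1` must not exceed `n0`.")
  if (any(n1 < 0)) abort("`n1` must be non-negative.")
  a <- eta_prime
  dn <- n0 - n1
  point <- 1 / (1 + a * n0 + (a * n0)^2)
  ifelse(a * dn < 1e-8,
         point,
         2 / (sqrt(3) * a * dn) *
           (atan((2 * a * n0 + 1) / sqrt(3)) -
              atan((2 * a * n1 + 1) / sqrt(3))))
}

# assemble a misrepair summary object from per-pathway tallies
new_misrepair_summary <- function(per_pathway, n_induced, n_unrepaired,
                                  eta_prime_used, eta_track_used = 0) {
  n_repaired <- sum(per_pathway$n_repaired)
  n_mis_binary <- sum(per_pathway$n_mis_binary)
  n_mis_process <- sum(per_pathway$n_mis_process)
  n_mis <- n_mis_binary + n_mis_process
  structure(
    list(
      n_induced = n_induced,
      n_repaired = n_repaired,
      n_unrepaired = n_unrepaired,
      n_correct = n_repaired - n_mis,
      n_mis = n_mis,
      n_mis_binary = n_mis_binary,
      n_mis_process = n_mis_process,
      p_correct = if (n_repaired > 0) 1 - n_mis / n_repaired else 1,
      per_pathway = per_pathway,
      eta_prime = eta_prime_used,
      eta_track = eta_track_used
    ),
    class = "misrepair_summary"
  )
}

#' @export
print.misrepair_summary <- function(x, ...) {
  cat(sprintf(
    "<misrepair_summary> induced %.4g, repaired %.4g, misrepaired %.4g (binary %.4g)\n",
    x$n_induced, x$n_repaired, x$n_mis, x$n_mis_binary))
  cat(sprintf("  P(correct) = %.4f, eta' = %.4g (track %.4g)\n",
              x$p_correct, x$eta_prime, x$eta_track))
  invisible(x)
}

#' Analytic misrepair for an arbitrary exposure protocol
#'
#' Computes expected correct and incorrect rejoining for any protocol by
#' stepping through the exact repair kinetics: within each step the break
#' population falls from `N0` (breaks present at the step start plus any
#' newly induced) to `N1`, and the interval correct-repair probability
#' [p_correct_partial()] is applied to the breaks repaired in the step.
#' Pathway fidelity factors `mu_x` multiply the correct-repair probability
#' of NHEJ and MMEJ repairs (HR is fully faithful); this process
#' infidelity is tallied separately from binary (proximity) misrepair
#' because only binary events rearrange chromosomes.  Steps are bounded so
#' that at most 5% of the present breaks repair per step, and the step
#' count is doubled until the misrepair total changes by less than 0.1%.
#'
#' For a single acute fraction this reduces exactly to
#' [p_correct_complete()].
#'
#' @param protocol A [dose_protocol()].
#' @param phenotype,geometry,params Model inputs.
#' @param phase Concrete cycle phase (default from the phenotype).
#' @param eta_track_value Intra-track interaction rate to add to
#'   `eta_prime` (0 for photons; see [eta_track()]).
#' @param n0_override Fixed initial break count for impulse protocols
#'   (replaces the expectation `kappa * dose`; used for track-number
#'   conditioning).
#' @param horizon Follow repair until this time (h) or until fewer than
#'   `1e-6` of the induced breaks remain repairable, whichever is first.
#' @return A `misrepair_summary`: induced/repaired/correct/misrepaired
#'   expected counts, the correct-repair probability and the interaction
#'   rates used, with a per-pathway breakdown.
#' @examples
#' misrepair_analytic(acute_exposure(2), radiation_phenotype(),
#'                    nucleus_geometry(), repair_parameters())
#' @export
misrepair_analytic <- function(protocol, phenotype, geometry, params,
                               phase = NULL, eta_track_value = 0,
                               n0_override = NULL, horizon = 4000) {
  phase <- phase %||% phenotype$cycle_phase
  if (phase == "asynchronous") {
    abort("resolve asynchronous phenotypes into phases first.")
  }
  assignment <- assign_pathways(phenotype, params, phase)
  ep <- eta_prime(geometry, params$sigma * geometry$radius) + eta_track_value

  kappa <- expected_dsb_count(1, phenotype$genome_size, geometry$dsb_yield)
  if (!is.null(n0_override)) {
    if (any(protocol$duration > 0) || nrow(protocol) > 1) {
      abort("`n0_override` is only meaningful for single-impulse protocols.")
    }
    kappa_eff <- n0_override / max(total_dose(protocol), 1e-300)
  } else {
    kappa_eff <- kappa
  }
  # Fast exact path for purely acute exposures (all dose in impulses at one
  # instant): substituting u = exp(-lambda_x t) turns the per-pathway
  # misrepair integral into int_0^1 (1 - pc(N(u))) du with N(u) known in
  # closed form, so no time stepping is needed.
  if (all(protocol$duration == 0) &&
      length(unique(protocol$start)) == 1L) {
    n0_tot <- kappa_eff * total_dose(protocol)
    p <- assignment$p
    lam <- assignment$lambda
    u_resid <- n0_tot * assignment$p_unrepaired
    n_at <- function(u, x) {
      # breaks present when pathway x has decayed to fraction u
      n <- u_resid
      for (y in names(p)) {
        if (p[[y]] > 0) n <- n + n0_tot * p[[y]] * u^(lam[[y]] / lam[[x]])
      }
      n
    }
    repaired <- n0_tot * p
    mis_binary <- setNames(numeric(3), names(p))
    pc_mean <- setNames(numeric(3), names(p))
    for (x in names(p)) {
      if (p[[x]] <= 0) next
      pc_mean[x] <- integrate(function(u) {
        n <- n_at(u, x)
        1 / (1 + ep * n + (ep * n)^2)
      }, 0, 1, rel.tol = 1e-10)$value
      mis_binary[x] <- repaired[[x]] * (1 - pc_mean[x]) *
        assignment$binary_eligible[[x]]
    }
    mis_process <- repaired * pc_mean * (1 - assignment$mu)
    per <- tibble(pathway = names(p),
                  n_repaired = as.numeric(repaired),
                  n_mis_binary = as.numeric(mis_binary),
                  n_mis_process = as.numeric(mis_process))
    return(new_misrepair_summary(per, n0_tot, u_resid, ep,
                                 eta_track_value))
  }

  eng <- kinetics_engine(protocol, assignment, kappa_eff)

  run_steps <- function(n_per_interval) {
    # step grid: breakpoints refined so each step repairs <= ~5% of breaks
    bp <- eng$breakpoints
    tmax <- max(horizon, protocol_end(protocol) + 1)
    grid <- numeric(0)
    # adaptive forward construction
    t <- 0
    lam_min <- min(assignment$lambda[assignment$p > 0], na.rm = TRUE)
    lam_max <- max(assignment$lambda[assignment$p > 0], na.rm = TRUE)
    if (!is.finite(lam_max)) lam_max <- 1
    repeat {
      grid <- c(grid, t)
      if (t >= tmax) break
      st <- eng$state_at(t)
      tot <- sum(st$N)
      inducing <- dose_rate_at(protocol, t + 1e-9) > 0
      if (tot > 0 || inducing) {
        lam_eff <- if (tot > 0) sum(assignment$lambda * st$N) / tot else
          lam_max
        # while dose is being delivered, fresh fast-repairing breaks set
        # the step scale even if the standing population is slow
        if (inducing) lam_eff <- max(lam_eff, lam_max)
        dt <- 0.05 / max(lam_eff, 1e-8) / n_per_interval
      } else {
        dt <- (tmax - t) / n_per_interval
      }
      dt <- max(dt, tmax / 5e4)
      nxt <- bp[bp > t + 1e-12]
      if (length(nxt) > 0) dt <- min(dt, nxt[1] - t)
      t <- min(t + dt, tmax)
      # early exit: effectively complete repair
      st2 <- eng$state_at(t)
      if (t > max(bp) && sum(st2$N) < 1e-6 * max(st2$I, 1)) {
        grid <- c(grid, t)
        break
      }
    }
    grid <- unique(grid)

    states <- lapply(grid, eng$state_at)
    mis_binary <- setNames(numeric(3), names(assignment$p))
    mis_process <- setNames(numeric(3), names(assignment$p))
    repaired <- setNames(numeric(3), names(assignment$p))
    for (i in seq_len(length(states) - 1)) {
      s0 <- states[[i]]
      s1 <- states[[i + 1]]
      dR <- s1$R - s0$R              # per-pathway breaks joined this step
      if (sum(dR) <= 0) next
      induced <- s1$I - s0$I
      n_start <- sum(s0$N) + s0$U + induced
      n_end <- sum(s1$N) + s1$U
      pc <- p_correct_partial(ep, n_start, min(n_end, n_start))
      repaired <- repaired + dR
      mis_binary <- mis_binary + dR * (1 - pc) * assignment$binary_eligible
      mis_process <- mis_process + dR * pc * (1 - assignment$mu)
    }
    last <- states[[length(states)]]
    # residue still physically present at the horizon counts as unrepaired
    list(per = tibble(pathway = names(assignment$p),
                      n_repaired = as.numeric(repaired),
                      n_mis_binary = as.numeric(mis_binary),
                      n_mis_process = as.numeric(mis_process)),
         n_induced = last$I,
         n_unrepaired = last$U + sum(last$N))
  }

  res <- run_steps(1)
  for (halvings in 1:4) {
    res2 <- run_steps(2^halvings)
    tot1 <- sum(res$per$n_mis_binary) + sum(res$per$n_mis_process)
    tot2 <- sum(res2$per$n_mis_binary) + sum(res2$per$n_mis_process)
    res <- res2
    if (abs(tot2 - tot1) <= 1e-3 * max(tot2, 1e-12)) break
  }

  new_misrepair_summary(res$per, res$n_induced, res$n_unrepaired,
                        ep, eta_track_value)
}
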