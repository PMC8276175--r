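#' Closed-form break kinetics after an acute exposure
#'
#' After an acute exposure inducing `n0` breaks, each pathway compartment
#' decays exponentially: the physical break count is
#' `n0 (p_f e^{-lambda_f t} + p_s e^{-lambda_s t} + p_m e^{-lambda_m t})`
#' plus the permanently unrepairable fraction.
#'
#' @param n0 Initial break count.
#' @param assignment A [assign_pathways()] result.
#' @param t Times in h (vector).
#' @return A tibble with `time`, per-pathway `n_phys_*`, `n_unrepairable`
#'   and `n_phys_total`.
#' @export
acute_physical_breaks <- function(n0, assignment, t) {
  stopifnot(inherits(assignment, "pathway_assignment"), n0 >= 0)
  if (any(t < 0)) abort("`t` must be non-negative.")
  p <- assignment$p
  l <- assignment$lambda
  tibble(
    time = t,
    n_phys_fast = n0 * p[["fast"]] * exp(-l[["fast"]] * t),
    n_phys_slow = n0 * p[["slow"]] * exp(-l[["slow"]] * t),
    n_phys_mmej = n0 * p[["mmej"]] * exp(-l[["mmej"]] * t),
    n_unrepairable = n0 * assignment$p_unrepaired + 0 * t
  ) |>
    dplyr::mutate(n_phys_total = .data$n_phys_fast + .data$n_phys_slow +
                    .data$n_phys_mmej + .data$n_unrepairable)
}

# two-exponential rise-and-fall of protein-bearing joined breaks, with the
# analytic nu -> lambda limit
prot_term <- function(n0p, lambda, nu, t) {
  if (abs(nu - lambda) < 1e-9 * lambda) {
    n0p * lambda * t * exp(-lambda * t)
  } else {
    n0p * lambda * (exp(-lambda * t) - exp(-nu * t)) / (nu - lambda)
  }
}

#' Closed-form focus kinetics after an acute exposure
#'
#' Joined breaks keep their repair-protein focus until the proteins clear
#' at rate `nu_x`, so visible foci are the sum of physical and
#' protein-bearing joined breaks.  Unrepairable breaks retain their focus
#' indefinitely.
#'
#' @inheritParams acute_physical_breaks
#' @return A tibble with per-pathway `n_prot_*`, `n_foci` and the physical
#'   counts of [acute_physical_breaks()].
#' @export
acute_foci <- function(n0, assignment, t) {
  out <- acute_physical_breaks(n0, assignment, t)
  p <- assignment$p
  l <- assignment$lambda
  nu <- assignment$nu
  out$n_prot_fast <- prot_term(n0 * p[["fast"]], l[["fast"]], nu[["fast"]], t)
  out$n_prot_slow <- prot_term(n0 * p[["slow"]], l[["slow"]], nu[["slow"]], t)
  out$n_prot_mmej <- prot_term(n0 * p[["mmej"]], l[["mmej"]], nu[["mmej"]], t)
  out$n_foci <- out$n_phys_total + out$n_prot_fast + out$n_prot_slow +
    out$n_prot_mmej
  out
}

# ---------------------------------------------------------------------------
# Exact piecewise propagation for arbitrary protocols.
#
# Within a segment of constant dose rate the system is linear:
#   N' = -lambda N + b,   P' = lambda N - nu P,
# with b the pathway's induction rate.  Both have closed-form solutions,
# so the solver propagates the exact state across an ordered sequence of
# breakpoints (segment edges and impulses) with no discretization error.

propagate_state <- function(state, dt, b_phys, b_unrep, lambda, nu) {
  if (dt <= 0) return(state)
  N0 <- state$N
  P0 <- state$P
  eL <- exp(-lambda * dt)
  eN <- exp(-nu * dt)
  Ninf <- ifelse(lambda > 0, b_phys / lambda, 0)
  N1 <- (N0 - Ninf) * eL + Ninf
  # P' = lambda N - nu P driven by the two N components
  trans <- ifelse(abs(nu - lambda) < 1e-9 * pmax(nu, lambda),
                  lambda * (N0 - Ninf) * dt * eL,
                  lambda * (N0 - Ninf) * (eL - eN) / (nu - lambda))
  steady <- ifelse(nu > 0, lambda * Ninf * (1 - eN) / nu, 0)
  P1 <- P0 * eN + trans + steady
  # cumulative joined breaks per pathway
  R1 <- state$R + (N0 - Ninf) * (1 - eL) + b_phys * dt
  list(N = N1, P = P1, R = R1,
       U = state$U + b_unrep * dt,
       I = state$I + (sum(b_phys) + b_unrep) * dt,
       t = state$t + dt)
}

apply_impulse <- function(state, n0, p, p_unrep) {
  state$N <- state$N + n0 * p
  state$U <- state$U + n0 * p_unrep
  state$I <- state$I + n0
  state
}

# Build the exact kinetics engine for a protocol.  Returns a function
# state_at(t) evaluating the exact state, plus the breakpoints.
kinetics_engine <- function(protocol, assignment, kappa) {
  p <- assignment$p
  lambda <- assignment$lambda
  nu <- assignment$nu
  p_un <- assignment$p_unrepaired

  # breakpoints: starts and ends of finite segments, impulse times
  imp <- protocol[protocol$duration == 0, , drop = FALSE]
  seg <- protocol[protocol$duration > 0, , drop = FALSE]
  bp <- sort(unique(c(0, imp$start, seg$start, seg$start + seg$duration)))

  zero_state <- list(N = setNames(numeric(3), names(p)),
                     P = setNames(numeric(3), names(p)),
                     R = setNames(numeric(3), names(p)),
                     U = 0, I = 0, t = 0)

  rate_in <- function(t) kappa * dose_rate_at(protocol, t)

  # precompute states at the breakpoints
  states <- vector("list", length(bp))
  st <- zero_state
  for (i in seq_along(bp)) {
    if (i > 1) {
      tm <- (bp[i - 1] + bp[i]) / 2
      rin <- rate_in(tm)
      st <- propagate_state(st, bp[i] - bp[i - 1], p * rin, p_un * rin,
                            lambda, nu)
    }
    # impulses fire at their breakpoint (state just after)
    for (j in seq_len(nrow(imp))) {
      if (abs(imp$start[j] - bp[i]) < 1e-12) {
        st <- apply_impulse(st, kappa * imp$dose[j], p, p_un)
      }
    }
    st$t <- bp[i]
    states[[i]] <- st
  }

  state_at <- function(t) {
    if (t < 0) abort("`t` must be non-negative.")
    i <- findInterval(t, bp)
    if (i == 0) return(zero_state)
    st <- states[[i]]
    if (t > bp[i]) {
      # dose rate is constant between breakpoints, so the midpoint between
      # bp[i] and t samples the right segment
      rin <- rate_in((bp[i] + t) / 2)
      st <- propagate_state(st, t - bp[i], p * rin, p_un * rin, lambda, nu)
    }
    st
  }

  list(state_at = state_at, breakpoints = bp, assignment = assignment,
       kappa = kappa)
}

state_row <- function(st) {
  tibble(
    time = st$t,
    n_phys_fast = st$N[["fast"]], n_phys_slow = st$N[["slow"]],
    n_phys_mmej = st$N[["mmej"]],
    n_prot_fast = st$P[["fast"]], n_prot_slow = st$P[["slow"]],
    n_prot_mmej = st$P[["mmej"]],
    n_unrepairable = st$U,
    cum_induced = st$I,
    cum_repaired = sum(st$R)
  )
}

#' Break and focus kinetics for an arbitrary exposure protocol
#'
#' Integrates the per-pathway rate equations
#' `dN_x/dt = -lambda_x N_x + p_x k D(t)` and
#' `dP_x/dt = lambda_x N_x - nu_x P_x` for a protocol of dose-rate
#' segments and acute impulses.  The forcing is piecewise constant, so the
#' solution is propagated exactly across segment boundaries (no numerical
#' integration error).  Proliferation during the exposure is not
#' modelled, so the curves describe quiescent or arrested populations.
#'
#' @param protocol A [dose_protocol()].
#' @param phenotype A [radiation_phenotype()].
#' @param geometry A [nucleus_geometry()].
#' @param params A [repair_parameters()].
#' @param phase Concrete cycle phase; defaults to the phenotype's phase
#'   (which must not be asynchronous here — mix the per-phase curves
#'   upstream).
#' @param times Output grid in h; default log-spaced over 0–48 h.
#' @param assignment Optional precomputed [assign_pathways()] result.
#' @return A `medras_kinetics` tibble: per-pathway physical and
#'   protein-bearing counts, unrepairable residual, totals, foci and the
#'   cumulative induced/repaired book-keeping columns.
#' @examples
#' kin <- repair_kinetics(acute_exposure(1), radiation_phenotype(),
#'                        nucleus_geometry(), repair_parameters())
#' @export
repair_kinetics <- function(protocol, phenotype, geometry, params,
                            phase = NULL, times = NULL, assignment = NULL) {
  stopifnot(inherits(protocol, "dose_protocol"))
  phase <- phase %||% phenotype$cycle_phase
  if (phase == "asynchronous") {
    abort("resolve asynchronous phenotypes into phases before computing kinetics.")
  }
  assignment <- assignment %||% assign_pathways(phenotype, params, phase)
  kappa <- expected_dsb_count(1, phenotype$genome_size, geometry$dsb_yield)
  eng <- kinetics_engine(protocol, assignment, kappa)
  if (is.null(times)) {
    t_hi <- max(48, protocol_end(protocol) + 24)
    times <- c(0, 10^seq(-2, log10(t_hi), length.out = 120))
  }
  times <- sort(unique(c(times, eng$breakpoints[eng$breakpoints <= max(times)])))
  rows <- dplyr::bind_rows(lapply(times, function(t) state_row(eng$state_at(t))))
  out <- rows |>
    dplyr::mutate(
      n_phys_total = .data$n_phys_fast + .data$n_phys_slow +
        .data$n_phys_mmej + .data$n_unrepairable,
      n_foci = .data$n_phys_total + .data$n_prot_fast + .data$n_prot_slow +
        .data$n_prot_mmej
    )
  structure(out,
            class = c("medras_kinetics", class(out)),
            protocol = protocol,
            assignment = assignment,
            kappa = kappa,
            engine = eng)
}

# First time at which the physical break count drops below `threshold`
# (checkpoint release).  Returns list(time, n) where n is the break count
# at release; if the plateau never falls below threshold, time = Inf and
# n is the count at `horizon`.
time_below_threshold <- function(engine, threshold, horizon = 2000) {
  n_at <- function(t) {
    st <- engine$state_at(t)
    sum(st$N) + st$U
  }
  t0 <- protocol_end_from_engine(engine)
  if (n_at(t0) < threshold) return(list(time = t0, n = n_at(t0)))
  if (n_at(horizon) >= threshold) {
    return(list(time = Inf, n = n_at(horizon)))
  }
  root <- uniroot(function(t) n_at(t) - threshold, c(t0, horizon),
                  tol = 1e-8)
  list(time = root$root, n = threshold)
}

protocol_end_from_engine <- function(engine) {
  max(engine$breakpoints)
}
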