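# Survival composition: lethal aberrations, mitotic catastrophe and
# apoptosis, each an exponential function of the relevant damage count,
# combined as independent mechanisms.

# survival components for one concrete phase given precomputed pieces
compose_survival <- function(phase, aberr, n_mitosis, n_g1, phenotype,
                             s_params) {
  early <- phase %in% c("G0", "G1")
  s_aberr <- if (early) {
    exp(-aberr$n_dicentric - aberr$n_deletion_large)
  } else {
    # post-replication: a single large deletion is no longer lethal, but
    # inter-arm events compromise segregation
    exp(-aberr$n_dicentric - aberr$n_interarm)
  }
  s_mitotic <- if (phase == "G0") 1 else exp(-s_params$phi * n_mitosis)
  s_apop <- if (phase == "G1") {
    psi <- if (phenotype$g1_arrest_competent) s_params$psi_full else
      s_params$psi_base
    exp(-psi * n_g1)
  } else {
    1  # apoptosis is modelled only for cycling G1 cells
  }
  tibble(phase = phase,
         s_aberration = s_aberr,
         s_mitotic = s_mitotic,
         s_apoptosis = s_apop,
         s_total = s_aberr * s_mitotic * s_apop,
         n_mitosis = n_mitosis,
         n_g1 = n_g1)
}

# full per-phase pipeline for a fixed initial break count n0 delivered by
# `protocol`; returns the one-row survival tibble for that phase
survival_one_phase <- function(phase, protocol, phenotype, geometry, params,
                               s_params, eta_track_value = 0,
                               n0_override = NULL) {
  assignment <- assign_pathways(phenotype, params, phase)
  kappa <- expected_dsb_count(1, phenotype$genome_size, geometry$dsb_yield)
  kappa_eff <- if (is.null(n0_override)) kappa else
    n0_override / max(total_dose(protocol), 1e-300)

  mis <- misrepair_analytic(protocol, phenotype, geometry, params,
                            phase = phase,
                            eta_track_value = eta_track_value,
                            n0_override = n0_override)
  # Lethal aberrations are fed by all misrepair: binary (proximity) events
  # and single-hit process-infidelity events.  The latter are the
  # dose-rate-independent component of aberration yields and dominate
  # killing in MMEJ-dependent (NHEJ-deficient) cells.
  sigma_abs <- params$sigma * geometry$radius
  aberr <- classify_misrepair(mis$n_mis, geometry, sigma_abs,
                              phenotype, s_params)

  eng <- kinetics_engine(protocol, assignment, kappa_eff)
  rel <- time_below_threshold(eng, s_params$checkpoint_threshold)
  n_mitosis <- rel$n

  n_g1 <- if (phase == "G1") kappa_eff * total_dose(protocol) else 0

  out <- compose_survival(phase, aberr, n_mitosis, n_g1, phenotype,
                          s_params)
  out$n_mis_binary <- mis$n_mis_binary
  out
}

#' Predicted survival for one exposure
#'
#' Runs the full chain damage -> kinetics -> misrepair -> aberrations ->
#' death for every cycle phase of the phenotype and returns per-phase and
#' phase-weighted survival.  Death mechanisms: lethal aberrations
#' (`exp(-N_dic - N_del>threshold)` before replication,
#' `exp(-N_dic - N_interarm)` after), mitotic catastrophe
#' (`exp(-phi N_m)` with `N_m` the physical breaks remaining when the G2
#' checkpoint releases, i.e. when fewer than `checkpoint_threshold`
#' remain), and apoptosis for cycling G1 cells
#' (`exp(-psi N_G1)`, `psi` selected by G1-arrest competence).
#'
#' For high-LET exposures with more than 0.5 expected DSBs per track the
#' track-number distribution is no longer ignorable: survival is then
#' averaged over a Poisson number of tracks delivering the prescribed
#' mean dose.
#'
#' @param dose Dose in Gy (scalar), or `NULL` when `protocol` is given.
#' @param phenotype A [radiation_phenotype()].
#' @param geometry A [nucleus_geometry()].
#' @param params A [repair_parameters()].
#' @param s_params A [survival_parameters()].
#' @param protocol A [dose_protocol()]; defaults to an acute exposure of
#'   `dose` Gy.
#' @param profile Optional [track_profile()] for ion exposures.
#' @param track_average Apply Poisson track-number averaging when the
#'   expected DSBs per track exceed 0.5 (default TRUE).
#' @return A tibble with one row per phase plus a `"combined"` row:
#'   `s_aberration`, `s_mitotic`, `s_apoptosis`, `s_total` and the damage
#'   counts behind them.
#' @examples
#' predict_survival(2, radiation_phenotype())
#' @export
predict_survival <- function(dose = NULL, phenotype = radiation_phenotype(),
                             geometry = nucleus_geometry(
                               genome_size = phenotype$genome_size),
                             params = repair_parameters(),
                             s_params = survival_parameters(),
                             protocol = NULL, profile = NULL,
                             track_average = TRUE) {
  protocol <- protocol %||% acute_exposure(dose)
  dose <- total_dose(protocol)
  phases <- resolve_phases(phenotype)

  eta_tr <- 0
  n_per_track <- 0
  if (!is.null(profile)) {
    sigma_abs <- params$sigma * geometry$radius
    eta_tr <- eta_track(profile, geometry, sigma_abs,
                        seed = 760813, n_pairs = 2e4)
    ein <- track_energy_in_nucleus(profile, geometry)
    n_per_track <- ein$total / geometry$e_dsb
  }

  one_phase_avg <- function(phase) {
    if (is.null(profile) || !track_average || n_per_track <= 0.5 ||
        any(protocol$duration > 0) || nrow(protocol) > 1) {
      return(survival_one_phase(phase, protocol, phenotype, geometry,
                                params, s_params, eta_tr))
    }
    # Poisson track-number averaging for acute high-LET impulses
    mu_tracks <- expected_dsb_count(dose, phenotype$genome_size,
                                    geometry$dsb_yield) / n_per_track
    k_lo <- qpois(1e-9, mu_tracks)
    k_max <- qpois(1 - 1e-9, mu_tracks)
    k <- k_lo:k_max
    w <- dpois(k, mu_tracks)
    w <- w / sum(w)
    one_k <- function(ki) {
      if (ki == 0) {
        return(tibble(phase = phase, s_aberration = 1, s_mitotic = 1,
                      s_apoptosis = 1, s_total = 1, n_mitosis = 0,
                      n_g1 = 0, n_mis_binary = 0))
      }
      survival_one_phase(phase, protocol, phenotype, geometry, params,
                         s_params, eta_tr,
                         n0_override = ki * n_per_track)
    }
    if (length(k) <= 13) {
      rows <- lapply(k, one_k)
    } else {
      # survival varies smoothly with the track count: evaluate on a
      # sub-grid and spline-interpolate the (log-scale) components
      k_eval <- unique(round(seq(max(k_lo, 0), k_max, length.out = 13)))
      ev <- lapply(k_eval, one_k)
      interp <- function(col) {
        y <- log(pmax(vapply(ev, function(r) r[[col]], numeric(1)), 1e-300))
        exp(stats::spline(k_eval, y, xout = k)$y)
      }
      lin <- function(col) stats::spline(
        k_eval, vapply(ev, function(r) r[[col]], numeric(1)), xout = k)$y
      cols <- list(s_aberration = interp("s_aberration"),
                   s_mitotic = interp("s_mitotic"),
                   s_apoptosis = interp("s_apoptosis"),
                   s_total = interp("s_total"),
                   n_mitosis = lin("n_mitosis"),
                   n_g1 = lin("n_g1"),
                   n_mis_binary = lin("n_mis_binary"))
      rows <- lapply(seq_along(k), function(i) {
        tibble(phase = phase,
               s_aberration = cols$s_aberration[i],
               s_mitotic = cols$s_mitotic[i],
               s_apoptosis = cols$s_apoptosis[i],
               s_total = cols$s_total[i],
               n_mitosis = cols$n_mitosis[i],
               n_g1 = cols$n_g1[i],
               n_mis_binary = cols$n_mis_binary[i])
      })
    }
    avg <- function(col) sum(w * vapply(rows, function(r) r[[col]],
                                        numeric(1)))
    tibble(phase = phase,
           s_aberration = avg("s_aberration"),
           s_mitotic = avg("s_mitotic"),
           s_apoptosis = avg("s_apoptosis"),
           s_total = avg("s_total"),
           n_mitosis = avg("n_mitosis"),
           n_g1 = avg("n_g1"),
           n_mis_binary = avg("n_mis_binary"))
  }

  rows <- dplyr::bind_rows(lapply(phases$phase, one_phase_avg))
  wts <- phases$weight
  combined <- tibble(
    phase = "combined",
    s_aberration = sum(wts * rows$s_aberration),
    s_mitotic = sum(wts * rows$s_mitotic),
    s_apoptosis = sum(wts * rows$s_apoptosis),
    s_total = sum(wts * rows$s_total),
    n_mitosis = sum(wts * rows$n_mitosis),
    n_g1 = sum(wts * rows$n_g1),
    n_mis_binary = sum(wts * rows$n_mis_binary)
  )
  out <- dplyr::bind_rows(rows, combined)
  structure(out, class = c("survival_result", class(out)),
            dose = dose, phenotype = phenotype)
}

#' Survival dose-response curve
#'
#' Evaluates [predict_survival()] over a dose grid, returning the
#' phase-weighted components at each dose.
#'
#' @param doses Dose grid in Gy.
#' @inheritParams predict_survival
#' @param protocol_fn Optional function `dose -> dose_protocol` for
#'   non-acute deliveries (e.g. a fixed dose rate).
#' @return A `dose_response` tibble: `dose_gy`, `s_aberration`,
#'   `s_mitotic`, `s_apoptosis`, `s_total`, with the generating closure
#'   stored as an attribute (used by [mid()]).
#' @examples
#' dr <- dose_response(c(0, 1, 2, 4), radiation_phenotype())
#' @export
dose_response <- function(doses, phenotype = radiation_phenotype(),
                          geometry = nucleus_geometry(
                            genome_size = phenotype$genome_size),
                          params = repair_parameters(),
                          s_params = survival_parameters(),
                          profile = NULL, protocol_fn = NULL,
                          track_average = TRUE) {
  if (any(doses < 0)) abort("`doses` must be non-negative.")
  fn <- function(d) {
    if (d == 0) {
      return(tibble(dose_gy = 0, s_aberration = 1, s_mitotic = 1,
                    s_apoptosis = 1, s_total = 1))
    }
    protocol <- if (is.null(protocol_fn)) acute_exposure(d) else
      protocol_fn(d)
    row <- predict_survival(phenotype = phenotype, geometry = geometry,
                            params = params, s_params = s_params,
                            protocol = protocol, profile = profile,
                            track_average = track_average)
    row <- row[row$phase == "combined", ]
    tibble(dose_gy = d, s_aberration = row$s_aberration,
           s_mitotic = row$s_mitotic, s_apoptosis = row$s_apoptosis,
           s_total = row$s_total)
  }
  out <- dplyr::bind_rows(lapply(sort(unique(doses)), fn))
  if (any(diff(out$s_total) > 1e-6)) {
    warn("survival is not monotone non-increasing in dose; check inputs.")
  }
  structure(out, class = c("dose_response", class(out)),
            survival_fn = function(d) fn(d)$s_total,
            phenotype = phenotype)
}

#' Mean inactivation dose
#'
#' The MID is the average dose required to kill a cell,
#' `integral of S(D) dD` over all doses.  For a model curve the stored
#' survival closure is integrated adaptively, extending the upper limit
#' until `S < s_floor` and adding an exponential-tail correction
#' estimated from the last decade of the curve.
#'
#' @param curve A [dose_response()] object.
#' @param s_floor Survival level treated as the start of the tail.
#' @param n_grid When supplied, integrate by composite Simpson's rule on
#'   this many points instead of adaptive quadrature — much cheaper for
#'   model curves whose every evaluation runs the full pipeline, at the
#'   cost of ~0.1% accuracy.
#' @return MID in Gy.
#' @seealso [mid_lq()] for the closed form of a linear-quadratic curve.
#' @export
mid <- function(curve, s_floor = 1e-7, n_grid = NULL) {
  stopifnot(inherits(curve, "dose_response"))
  s_fn <- attr(curve, "survival_fn")
  d_hi <- max(max(curve$dose_gy), 1)
  s_hi <- s_fn(d_hi)
  while (s_hi > s_floor) {
    d_hi <- d_hi * 2
    s_hi <- s_fn(d_hi)
    if (d_hi > 1e4) {
      abort("survival curve does not decay; cannot integrate the MID tail.")
    }
  }
  core <- if (is.null(n_grid)) {
    integrate(function(d) vapply(d, s_fn, numeric(1)), 0, d_hi,
              rel.tol = 1e-6, subdivisions = 200L)$value
  } else {
    n <- 2L * ceiling(n_grid / 2)  # Simpson needs an even interval count
    dd <- seq(0, d_hi, length.out = n + 1)
    ss <- vapply(dd, s_fn, numeric(1))
    h <- dd[2] - dd[1]
    h / 3 * (ss[1] + ss[n + 1] + 4 * sum(ss[seq(2, n, 2)]) +
               2 * sum(ss[seq(3, n - 1, 2)]))
  }
  # exponential tail from the last decade of decay
  d_ref <- d_hi * 0.8
  s_ref <- s_fn(d_ref)
  slope <- log(s_ref / s_hi) / (d_hi - d_ref)
  tail <- if (slope > 0) s_hi / slope else 0
  core + tail
}

#' Closed-form MID of a linear-quadratic survival curve
#'
#' `integral exp(-a D - b D^2) dD = sqrt(pi / (4 b)) exp(a^2 / (4 b))
#' erfc(a / (2 sqrt(b)))`; reduces to `1 / a` at `b = 0`.
#'
#' @param alpha,beta LQ parameters (Gy^-1, Gy^-2).
#' @return MID in Gy.
#' @examples
#' mid_lq(1, 0)    # 1
#' mid_lq(0.5, 0.05)
#' @export
mid_lq <- function(alpha, beta) {
  if (alpha <= 0 && beta <= 0) abort("need alpha > 0 or beta > 0.")
  if (beta <= 0) return(1 / alpha)
  sqrt(pi / (4 * beta)) * exp(alpha^2 / (4 * beta)) *
    erfc(alpha / (2 * sqrt(beta)))
}

#' Relative biological effectiveness from MID ratios
#'
#' @param reference Reference-quality [dose_response()] (e.g. X-rays).
#' @param test Test-quality [dose_response()].
#' @return `RBE = MID_reference / MID_test`.
#' @export
rbe_mid <- function(reference, test) {
  mid(reference) / mid(test)
}

#' Linear-quadratic summary fit of a dose-response curve
#'
#' Least-squares fit of `log S = -alpha D - beta D^2` over the stored
#' dose grid (a descriptive summary only; the model itself is not LQ).
#'
#' @param curve A [dose_response()].
#' @param d_max Fit range upper limit in Gy.
#' @return A list with `alpha`, `beta`.
#' @export
fit_lq <- function(curve, d_max = Inf) {
  stopifnot(inherits(curve, "dose_response"))
  df <- curve[curve$dose_gy > 0 & curve$dose_gy <= d_max &
                curve$s_total > 0, ]
  if (nrow(df) < 2) abort("need at least two positive-dose points to fit.")
  y <- -log(df$s_total)
  X <- cbind(df$dose_gy, df$dose_gy^2)
  cf <- stats::coef(stats::lm.fit(X, y))
  list(alpha = unname(cf[1]), beta = unname(cf[2]))
}
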