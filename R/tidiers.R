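# broom-style tidiers for fitted / summarized objects.

#' Tidy a misrepair summary
#'
#' @param x A `misrepair_summary`.
#' @param ... Unused.
#' @return A tibble with one row per repair pathway (joined counts,
#'   binary and process misrepair).
#' @export
tidy.misrepair_summary <- function(x, ...) {
  x$per_pathway
}

#' @rdname tidy.misrepair_summary
#' @export
glance.misrepair_summary <- function(x, ...) {
  tibble(n_induced = x$n_induced, n_repaired = x$n_repaired,
         n_unrepaired = x$n_unrepaired, n_correct = x$n_correct,
         n_mis = x$n_mis, n_mis_binary = x$n_mis_binary,
         n_mis_process = x$n_mis_process, p_correct = x$p_correct,
         eta_prime = x$eta_prime, eta_track = x$eta_track)
}

#' Tidy a dose-response curve
#'
#' @param x A `dose_response`.
#' @param ... Unused.
#' @return The per-dose survival tibble (`tidy`) or a one-row model
#'   summary with the MID and a descriptive LQ fit (`glance`).
#' @export
tidy.dose_response <- function(x, ...) {
  as_tibble(x)
}

#' @rdname tidy.dose_response
#' @param n_grid Passed to [mid()].
#' @export
glance.dose_response <- function(x, n_grid = 24, ...) {
  lq <- tryCatch(fit_lq(x), error = function(e) list(alpha = NA_real_,
                                                     beta = NA_real_))
  tibble(mid_gy = mid(x, n_grid = n_grid),
         alpha = lq$alpha, beta = lq$beta,
         min_survival = min(x$s_total))
}

#' Tidy a repair-event log
#'
#' @param x A `repair_event_log`.
#' @param ... Unused.
#' @return The event tibble (`tidy`); a one-row run summary (`glance`).
#' @export
tidy.repair_event_log <- function(x, ...) {
  as_tibble(x)
}

#' @rdname tidy.repair_event_log
#' @export
glance.repair_event_log <- function(x, ...) {
  n <- nrow(attr(x, "pattern"))
  tibble(n_breaks = n,
         n_events = nrow(x),
         n_correct = sum(x$same_dsb),
         n_mis = sum(!x$same_dsb),
         n_unrepaired = length(attr(x, "unrepaired")))
}
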