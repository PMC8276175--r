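#' Map a phenotype to repair-pathway probabilities and rates
#'
#' Breaks are simple (probability `1 - p_complex`) or complex.  Simple
#' breaks prefer NHEJ in every phase ("fast" kinetics).  Complex breaks
#' prefer NHEJ after end processing in G0/G1 and HR in S/G2 ("slow"
#' kinetics).  When a break's preferred pathway is unavailable, a fraction
#' `p_fail` is rescued by backup MMEJ ("very slow" kinetics); the remainder
#' stays on an available slow route, or permanently fails to repair when no
#' route is left.  A `long_term_failure_fraction` of breaks is removed
#' proportionally from every pathway and never repairs.
#'
#' In repair-competent cells this reduces to `p_f = 1 - p_complex`,
#' `p_s = p_complex`, `p_m = 0`; e.g. an HR-deficient cell in G2 has
#' `p_s = p_complex (1 - p_fail)` and `p_m = p_complex p_fail`.
#'
#' @param phenotype A [radiation_phenotype()].
#' @param params A [repair_parameters()].
#' @param phase A single concrete phase (`"G0"`, `"G1"`, `"S"`, `"G2"`);
#'   asynchronous populations must be resolved first with
#'   [resolve_phases()].
#' @param override Optional named list overriding the class-conditional
#'   routing table, with elements `simple` and/or `complex`, each a named
#'   numeric vector over `c(fast, slow, mmej, fail)` summing to 1.
#' @return An object of class `pathway_assignment`: absolute pathway
#'   probabilities `p` (`fast`, `slow`, `mmej`), the unrepaired fraction
#'   `p_unrepaired`, per-pathway rates `lambda` and focus-clearance rates
#'   `nu`, per-pathway fidelity factors `mu`, the identity of the slow
#'   route, and the class-conditional routing table.
#' @examples
#' assign_pathways(radiation_phenotype(), repair_parameters(), "G1")
#' @export
assign_pathways <- function(phenotype, params, phase, override = NULL) {
  stopifnot(inherits(phenotype, "radiation_phenotype"),
            inherits(params, "repair_parameters"))
  if (!is.character(phase) || length(phase) != 1L ||
      !phase %in% c("G0", "G1", "S", "G2")) {
    abort("`phase` must be one of G0, G1, S, G2 (resolve asynchronous phenotypes first).")
  }
  late <- phase %in% c("S", "G2")
  nhej <- phenotype$nhej_competent
  hr <- phenotype$hr_competent && late  # no sister chromatid before S
  p_fail <- params$p_fail

  # routing of one break class given (preferred available, alternative slow
  # route available): returns probabilities over fast/slow/mmej/fail
  route <- function(preferred_ok, slow_ok, preferred_kind) {
    out <- c(fast = 0, slow = 0, mmej = 0, fail = 0)
    if (preferred_ok) {
      out[preferred_kind] <- 1
    } else if (slow_ok) {
      out["mmej"] <- p_fail
      out["slow"] <- 1 - p_fail
    } else {
      out["mmej"] <- p_fail
      out["fail"] <- 1 - p_fail
    }
    out
  }

  # Simple breaks: preferred NHEJ (fast); if NHEJ is lost, HR can act as the
  # slow fallback in S/G2.  Complex breaks: preferred route is slow NHEJ in
  # G0/G1 and HR in S/G2; when HR is lost in S/G2 slow NHEJ remains the
  # fallback slow route.
  simple <- route(nhej, slow_ok = hr, preferred_kind = "fast")
  complex_ <- if (!late) {
    route(nhej, slow_ok = FALSE, preferred_kind = "slow")
  } else {
    route(hr, slow_ok = nhej, preferred_kind = "slow")
  }

  # identity of whatever populates the slow compartment in this state
  slow_route <- if (late && hr) "HR" else if (nhej) "NHEJ" else NA_character_

  if (!is.null(override)) {
    for (cls in names(override)) {
      v <- override[[cls]]
      if (!setequal(names(v), c("fast", "slow", "mmej", "fail")) ||
          abs(sum(v) - 1) > 1e-9 || any(v < 0)) {
        abort("routing override rows must be named fast/slow/mmej/fail and sum to 1.")
      }
      if (cls == "simple") simple <- v[c("fast", "slow", "mmej", "fail")]
      else if (cls == "complex") complex_ <- v[c("fast", "slow", "mmej", "fail")]
      else abort(sprintf("unknown routing override class `%s`.", cls))
    }
  }

  pc <- params$p_complex
  mix <- (1 - pc) * simple + pc * complex_
  flt <- phenotype$long_term_failure_fraction
  p <- (1 - flt) * mix[c("fast", "slow", "mmej")]
  p_unrepaired <- (1 - flt) * mix[["fail"]] + flt

  routing <- rbind(simple = simple, complex = complex_)

  structure(
    list(
      phase = phase,
      p = p,
      p_unrepaired = p_unrepaired,
      lambda = c(fast = params$lambda_f, slow = params$lambda_s,
                 mmej = params$lambda_m),
      nu = c(fast = params$nu_f, slow = params$nu_s, mmej = params$nu_m),
      mu = c(fast = params$mu_nhej,
             slow = if (identical(slow_route, "HR")) 1 else params$mu_nhej,
             mmej = params$mu_mmej),
      # HR rejoining is assumed always correct, so slow breaks in S/G2 do
      # not take part in binary misrepair
      binary_eligible = c(fast = TRUE,
                          slow = !identical(slow_route, "HR"),
                          mmej = TRUE),
      slow_route = slow_route,
      routing = routing,
      long_term_failure_fraction = flt
    ),
    class = "pathway_assignment"
  )
}

#' @export
print.pathway_assignment <- function(x, ...) {
  cat(sprintf("<pathway_assignment> phase %s (slow route: %s)\n",
              x$phase, x$slow_route))
  cat(sprintf("  p_fast=%.4g p_slow=%.4g p_mmej=%.4g unrepaired=%.4g\n",
              x$p[["fast"]], x$p[["slow"]], x$p[["mmej"]], x$p_unrepaired))
  invisible(x)
}
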