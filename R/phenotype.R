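#' Minimal radiation phenotype of a cell line
#'
#' The radiation phenotype is the complete cell-specific input to the model:
#' a handful of measurable features which replace per-cell-line fitting
#' parameters.  Everything downstream — pathway assignment, repair kinetics,
#' misrepair, aberration yields and survival — is predicted from these
#' fields together with the shared (cell-independent) model parameters.
#'
#' @param genome_size Total genome length in MBP (e.g. 6100 for a diploid
#'   human cell).
#' @param n_chromosomes Number of chromosomes in the nucleus (46 for human).
#' @param nhej_competent Is non-homologous end joining available?
#' @param hr_competent Is homologous recombination available (used in S/G2
#'   once a sister chromatid exists)?
#' @param g1_arrest_competent Is the G1/S damage checkpoint (p53 axis)
#'   functional?  Selects the full versus the residual apoptosis rate.
#' @param cycle_phase Phase at irradiation: `"G0"`, `"G1"`, `"S"`, `"G2"`,
#'   or `"asynchronous"`.
#' @param phase_fractions Named numeric vector of phase weights, only used
#'   (and then required to sum to 1) when `cycle_phase = "asynchronous"`.
#'   Defaults to `c(G1 = 0.6, S = 0.25, G2 = 0.15)`.
#' @param long_term_failure_fraction Fraction of breaks that permanently
#'   fail to repair (ATM-like signalling defect).  0 in repair-proficient
#'   cells; 0.22 reproduces the plateau seen in ATM-deficient lines.
#'
#' @return An object of class `radiation_phenotype`.
#' @examples
#' human <- radiation_phenotype()
#' atm   <- radiation_phenotype(long_term_failure_fraction = 0.22)
#' @export
radiation_phenotype <- function(genome_size = 6100,
                                n_chromosomes = 46,
                                nhej_competent = TRUE,
                                hr_competent = TRUE,
                                g1_arrest_competent = TRUE,
                                cycle_phase = c("G1", "G0", "S", "G2",
                                                "asynchronous"),
                                phase_fractions = NULL,
                                long_term_failure_fraction = 0) {
  cycle_phase <- match.arg(cycle_phase)
  check_number(genome_size, "genome_size", min = 1e-6)
  check_number(n_chromosomes, "n_chromosomes", min = 1)
  check_flag(nhej_competent, "nhej_competent")
  check_flag(hr_competent, "hr_competent")
  check_flag(g1_arrest_competent, "g1_arrest_competent")
  check_number(long_term_failure_fraction, "long_term_failure_fraction",
               min = 0, max = 1)
  if (cycle_phase == "asynchronous") {
    if (is.null(phase_fractions)) {
      phase_fractions <- c(G1 = 0.6, S = 0.25, G2 = 0.15)
    }
    if (is.null(names(phase_fractions)) ||
        !all(names(phase_fractions) %in% c("G0", "G1", "S", "G2"))) {
      abort("`phase_fractions` must be named with phases G0/G1/S/G2.")
    }
    if (abs(sum(phase_fractions) - 1) > 1e-9) {
      abort("`phase_fractions` must sum to 1 for an asynchronous population.")
    }
    if (any(phase_fractions < 0)) abort("`phase_fractions` must be >= 0.")
  } else if (!is.null(phase_fractions)) {
    abort("`phase_fractions` is only meaningful when cycle_phase = \"asynchronous\".")
  }
  structure(
    list(
      genome_size = genome_size,
      n_chromosomes = as.integer(n_chromosomes),
      nhej_competent = nhej_competent,
      hr_competent = hr_competent,
      g1_arrest_competent = g1_arrest_competent,
      cycle_phase = cycle_phase,
      phase_fractions = phase_fractions,
      long_term_failure_fraction = long_term_failure_fraction
    ),
    class = "radiation_phenotype"
  )
}

#' @export
print.radiation_phenotype <- function(x, ...) {
  cat("<radiation_phenotype>\n")
  cat(sprintf("  genome: %g MBP over %d chromosomes\n",
              x$genome_size, x$n_chromosomes))
  cat(sprintf("  pathways: NHEJ=%s HR=%s, G1 arrest=%s\n",
              x$nhej_competent, x$hr_competent, x$g1_arrest_competent))
  cat(sprintf("  phase: %s", x$cycle_phase))
  if (x$cycle_phase == "asynchronous") {
    cat(" (", paste(sprintf("%s=%.2g", names(x$phase_fractions),
                            x$phase_fractions), collapse = ", "), ")",
        sep = "")
  }
  cat("\n")
  if (x$long_term_failure_fraction > 0) {
    cat(sprintf("  long-term repair failure: %.0f%% of breaks\n",
                100 * x$long_term_failure_fraction))
  }
  invisible(x)
}

#' Resolve a phenotype into concrete cycle phases and weights
#'
#' A single-phase phenotype maps to itself with weight 1; an asynchronous
#' population maps to its configured phase mixture.  All endpoint
#' calculations are phase-weighted mixtures over this list.
#'
#' @param phenotype A [radiation_phenotype()].
#' @return A tibble with columns `phase` and `weight` (summing to 1).
#' @export
resolve_phases <- function(phenotype) {
  stopifnot(inherits(phenotype, "radiation_phenotype"))
  if (phenotype$cycle_phase != "asynchronous") {
    return(tibble(phase = phenotype$cycle_phase, weight = 1))
  }
  if (is.null(phenotype$phase_fractions)) {
    abort("asynchronous phenotype without `phase_fractions`.")
  }
  tibble(phase = names(phenotype$phase_fractions),
         weight = as.numeric(phenotype$phase_fractions))
}
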