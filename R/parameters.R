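#' Shared DNA-repair model parameters
#'
#' The global best-fit parameter set of the repair model.  These values are
#' shared by all cells: nothing in them is cell-line specific.  Defaults
#' are the published best-fit values and should normally be left alone.
#'
#' @param sigma Rejoining range of break ends, expressed as a fraction of
#'   the nucleus radius R.
#' @param mu_nhej,mu_mmej Pathway fidelity factors: the probability that a
#'   correctly paired NHEJ / MMEJ rejoining is also sequence-faithful.
#'   HR is implicitly fully faithful.
#' @param p_mut Point-mutation probability when a break is correctly
#'   repaired inside a gene.
#' @param p_complex Probability that a break is complex at creation.
#' @param p_fail Probability that a break whose preferred pathway is
#'   unavailable is rescued by backup MMEJ (the remainder stays on an
#'   available slow route, or fails when none exists).
#' @param lambda_f,lambda_s,lambda_m Repair rates (h^-1) of the fast,
#'   slow and MMEJ break populations.
#' @param nu_f,nu_s Repair-protein (focus) clearance rates (h^-1) for
#'   fast- and slow-repaired breaks.  MMEJ foci use `nu_s` (no separate
#'   clearance rate is defined for MMEJ; configurable here).
#' @param nu_m Focus clearance rate for MMEJ-repaired breaks; defaults to
#'   `nu_s`.
#' @return An object of class `repair_parameters`.
#' @examples
#' repair_parameters()
#' @export
repair_parameters <- function(sigma = 0.0418,
                              mu_nhej = 0.985,
                              mu_mmej = 0.44,
                              p_mut = 0.046,
                              p_complex = 0.43,
                              p_fail = 0.74,
                              lambda_f = 2.1,
                              lambda_s = 0.26,
                              lambda_m = 0.0085,
                              nu_f = 8.1,
                              nu_s = 0.41,
                              nu_m = nu_s) {
  for (nm in c("mu_nhej", "mu_mmej", "p_mut", "p_complex", "p_fail")) {
    check_number(get(nm), nm, min = 0, max = 1)
  }
  check_number(sigma, "sigma", min = 1e-12)
  for (nm in c("lambda_f", "lambda_s", "lambda_m", "nu_f", "nu_s", "nu_m")) {
    if (get(nm) <= 0) abort(sprintf("rate `%s` must be > 0.", nm))
  }
  structure(
    list(sigma = sigma, mu_nhej = mu_nhej, mu_mmej = mu_mmej,
         p_mut = p_mut, p_complex = p_complex, p_fail = p_fail,
         lambda_f = lambda_f, lambda_s = lambda_s, lambda_m = lambda_m,
         nu_f = nu_f, nu_s = nu_s, nu_m = nu_m),
    class = "repair_parameters"
  )
}

#' Cell-death model parameters
#'
#' @param phi Mitotic-catastrophe rate per DSB present at mitosis.
#' @param psi_full Apoptosis rate per G1-induced DSB in cells with a
#'   functional G1 arrest (p53-competent).
#' @param psi_base Residual apoptosis rate when G1 arrest is dysfunctional.
#' @param checkpoint_threshold DSB count below which the G2 damage
#'   checkpoint releases cells into mitosis.
#' @param large_deletion_threshold Deletion size (MBP) at and above which a
#'   deletion is counted as lethal.
#' @return An object of class `survival_parameters`.
#' @export
survival_parameters <- function(phi = 0.014,
                                psi_full = 0.012,
                                psi_base = 0.0007,
                                checkpoint_threshold = 20,
                                large_deletion_threshold = 3) {
  check_number(phi, "phi", min = 1e-12)
  check_number(psi_full, "psi_full", min = 1e-12)
  check_number(psi_base, "psi_base", min = 1e-12)
  if (psi_base >= psi_full) abort("`psi_base` must be < `psi_full`.")
  check_number(checkpoint_threshold, "checkpoint_threshold", min = 0)
  check_number(large_deletion_threshold, "large_deletion_threshold", min = 0)
  structure(
    list(phi = phi, psi_full = psi_full, psi_base = psi_base,
         checkpoint_threshold = checkpoint_threshold,
         large_deletion_threshold = large_deletion_threshold),
    class = "survival_parameters"
  )
}

#' Nucleus geometry and DSB-yield calibration
#'
#' The nucleus is a sphere of water at unit density.  Its default radius is
#' not free: it is fixed by the requirement that one Gray deposits exactly
#' enough energy to create the expected number of DSBs at `e_dsb` keV per
#' break.  For the reference human genome (6100 MBP at 5.738 DSB/GBP/Gy,
#' i.e. 35 DSB/Gy) and `e_dsb = 56.5` keV this gives R = 4.23 um.
#' Chromosome territories are spheres of radius `R / n_chromosomes^(1/3)`.
#'
#' @param genome_size Genome length in MBP used for the dose-energy
#'   calibration (defaults to the human reference 6100 MBP).
#' @param e_dsb Energy (keV) which on average creates one DSB, whether
#'   spread uniformly or clustered along a track.
#' @param dsb_yield DSB yield in DSB per GBP per Gy.
#' @param radius Nucleus radius in um; computed from the calibration when
#'   `NULL`.
#' @return An object of class `nucleus_geometry` with fields `radius`,
#'   `volume`, `e_dsb`, `dsb_yield`, `genome_size`.
#' @examples
#' nucleus_geometry()$radius  # 4.23 um
#' @export
nucleus_geometry <- function(genome_size = 6100,
                             e_dsb = 56.5,
                             dsb_yield = 5.738,
                             radius = NULL) {
  check_number(genome_size, "genome_size", min = 1e-6)
  check_number(e_dsb, "e_dsb", min = 1e-12)
  check_number(dsb_yield, "dsb_yield", min = 1e-12)
  dsb_per_gy <- dsb_yield * genome_size / 1000
  if (is.null(radius)) {
    volume <- dsb_per_gy * e_dsb / KEV_PER_UM3_PER_GY
    radius <- (3 * volume / (4 * pi))^(1 / 3)
  } else {
    check_number(radius, "radius", min = 1e-12)
    volume <- 4 / 3 * pi * radius^3
  }
  structure(
    list(radius = radius, volume = volume, e_dsb = e_dsb,
         dsb_yield = dsb_yield, genome_size = genome_size),
    class = "nucleus_geometry"
  )
}

#' Chromosome-territory radius for a geometry
#'
#' @param geometry A [nucleus_geometry()].
#' @param n_chromosomes Chromosome count.
#' @return Territory radius in um, `R / n_c^(1/3)`.
#' @export
chromosome_radius <- function(geometry, n_chromosomes) {
  stopifnot(inherits(geometry, "nucleus_geometry"))
  geometry$radius / n_chromosomes^(1 / 3)
}

#' @export
print.repair_parameters <- function(x, ...) {
  cat("<repair_parameters>\n")
  print(unlist(x))
  invisible(x)
}

#' @export
print.survival_parameters <- function(x, ...) {
  cat("<survival_parameters>\n")
  print(unlist(x))
  invisible(x)
}

#' @export
print.nucleus_geometry <- function(x, ...) {
  cat(sprintf("<nucleus_geometry> R = %.4g um, V = %.4g um^3, E_DSB = %g keV\n",
              x$radius, x$volume, x$e_dsb))
  invisible(x)
}
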