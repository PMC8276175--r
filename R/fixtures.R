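#' Synthetic fixture generator
#'
#' Produces small, fully reproducible damage inputs for testing and
#' demonstration: uniform low-LET patterns, clustered patterns around a
#' parametric synthetic track (core + 1/r^2 penumbra — not a
#' track-structure simulation), and toy SDD files on disk.  The same seed
#' always yields byte-identical output.
#'
#' @param kind `"uniform"`, `"clustered-track"` or `"toy-sdd"`.
#' @param dose Dose in Gy.
#' @param seed RNG seed (required for reproducibility).
#' @param dir Directory for file output (`"toy-sdd"`); created if needed.
#' @param let LET (keV/um) of the synthetic track for
#'   `"clustered-track"`.
#' @param phenotype,geometry,params Model inputs.
#' @return For pattern kinds, a `damage_pattern`; for `"toy-sdd"`, a list
#'   with the pattern and the written file `path`.
#' @examples
#' fx <- generate_fixture_suite("uniform", dose = 2, seed = 42)
#' @export
generate_fixture_suite <- function(kind = c("uniform", "clustered-track",
                                            "toy-sdd"),
                                   dose = 2, seed = 1, dir = tempdir(),
                                   let = 50,
                                   phenotype = radiation_phenotype(),
                                   geometry = nucleus_geometry(
                                     genome_size = phenotype$genome_size),
                                   params = repair_parameters()) {
  kind <- match.arg(kind)
  switch(
    kind,
    "uniform" = generate_uniform(dose, phenotype, geometry, params,
                                 seed = seed),
    "clustered-track" = {
      profile <- synthetic_track_profile(let)
      generate_track_pattern(dose, profile, phenotype, geometry, params,
                             seed = seed)
    },
    "toy-sdd" = {
      pattern <- generate_uniform(dose, phenotype, geometry, params,
                                  seed = seed)
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      path <- file.path(dir, sprintf("toy_sdd_seed%d.txt", seed))
      write_sdd(sdd_from_pattern(pattern, dose = dose), path)
      list(pattern = pattern, path = path)
    }
  )
}
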