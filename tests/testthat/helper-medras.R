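# Shared fixtures: default model objects and hand-built damage patterns.

human <- radiation_phenotype()
geo <- nucleus_geometry()
rp <- repair_parameters()
sp <- survival_parameters()
sigma_abs <- rp$sigma * geo$radius

# a pattern at explicit positions (all simple breaks unless stated)
fixed_pattern <- function(pos, chromosome = NULL, complex = FALSE,
                          genomic_coord = NULL, induction_time = 0,
                          phenotype = human, geometry = geo) {
  pos <- matrix(pos, ncol = 3)
  n <- nrow(pos)
  medras:::new_damage_pattern(
    tibble::tibble(
      id = seq_len(n),
      x = pos[, 1], y = pos[, 2], z = pos[, 3],
      chromosome = as.integer(chromosome %||% seq_len(n)),
      genomic_coord = genomic_coord %||% rep(10, n),
      complex = rep_len(complex, n),
      induction_time = rep_len(induction_time, n),
      track_id = -1L),
    geometry, phenotype, "fixture")
}

`%||%` <- rlang::`%||%`
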