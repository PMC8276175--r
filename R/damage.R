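#' Expected DSB count for a dose
#'
#' All radiation qualities are assumed to produce the same number of DSBs
#' per unit dose: `dose * yield * genome_size / 1000` (yield is per GBP).
#' For the human reference genome this is 35 DSB/Gy.
#'
#' @param dose Dose in Gy.
#' @param genome_size Genome length in MBP.
#' @param dsb_yield Yield in DSB per GBP per Gy.
#' @return Expected DSB count.
#' @examples
#' expected_dsb_count(1, 6100)  # 35
#' @export
expected_dsb_count <- function(dose, genome_size = 6100, dsb_yield = 5.738) {
  if (any(dose < 0)) abort("`dose` must be non-negative.")
  check_number(genome_size, "genome_size", min = 1e-6)
  dose * dsb_yield * genome_size / 1000
}

# Construct the damage-pattern tibble with its metadata.  A pattern is a
# tibble of per-break records plus geometry/phenotype attributes.
new_damage_pattern <- function(breaks, geometry, phenotype, provenance,
                               n_tracks = NA_integer_) {
  pat <- as_tibble(breaks)
  structure(pat,
            class = c("damage_pattern", class(pat)),
            geometry = geometry,
            phenotype = phenotype,
            provenance = provenance,
            n_tracks = n_tracks)
}

empty_breaks <- function() {
  tibble(id = integer(), x = numeric(), y = numeric(), z = numeric(),
         chromosome = integer(), genomic_coord = numeric(),
         complex = logical(), induction_time = numeric(),
         track_id = integer())
}

# Uniform points inside a sphere of radius R.
runif_sphere <- function(n, radius) {
  r <- radius * runif(n)^(1 / 3)
  u <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - u^2))
  cbind(x = r * s * cos(phi), y = r * s * sin(phi), z = r * u)
}

# Chromosome and genomic-coordinate assignment.  Two models:
#  - "territory" (default): chromosomes occupy compact territories; each
#    break belongs to the nearest of n_c territory centres (drawn once per
#    pattern inside the nucleus).  This makes nearby breaks share a
#    chromosome, as the analytic intra-chromosome model assumes.
#  - "uniform": chromosome drawn independently of position, with
#    probability proportional to its (equal) length.
# The genomic coordinate is uniform along the chromosome in both models.
assign_chromosomes <- function(n, phenotype, positions = NULL,
                               geometry = NULL,
                               model = c("territory", "uniform")) {
  model <- match.arg(model)
  n_c <- phenotype$n_chromosomes
  len <- phenotype$genome_size / n_c
  chromosome <- if (model == "territory" && !is.null(positions) && n > 0) {
    centres <- runif_sphere(n_c, 0.9 * geometry$radius)
    d2 <- outer(rowSums(positions^2), rowSums(centres^2), "+") -
      2 * positions %*% t(centres)
    max.col(-d2, ties.method = "first")
  } else {
    sample.int(n_c, n, replace = TRUE)
  }
  list(chromosome = as.integer(chromosome),
       genomic_coord = runif(n, 0, len),
       chrom_length = len)
}

#' Generate a uniform (low-LET) damage pattern
#'
#' Sparsely ionizing radiation (X-rays, energetic electrons) is modelled as
#' a uniform distribution of DSBs in the spherical nucleus.  The break
#' count is Poisson with mean [expected_dsb_count()]; complexity is
#' Bernoulli(`p_complex`) at creation.
#'
#' @param dose Dose in Gy.
#' @param phenotype A [radiation_phenotype()].
#' @param geometry A [nucleus_geometry()].
#' @param params A [repair_parameters()].
#' @param seed RNG seed for reproducibility (`NULL` uses the session RNG).
#' @param induction_time Induction time (h) stamped on the breaks.
#' @param n_breaks Optional fixed break count, overriding Poisson sampling
#'   (useful for conditioning studies).
#' @param chromosome_model `"territory"` (breaks share the chromosome of
#'   their nearest territory centre) or `"uniform"` (position-independent
#'   assignment).
#' @return A `damage_pattern` tibble with columns `id`, `x`, `y`, `z` (um),
#'   `chromosome`, `genomic_coord` (MBP), `complex`, `induction_time` (h),
#'   `track_id` (-1 for uniform damage).
#' @examples
#' pat <- generate_uniform(1, radiation_phenotype(), nucleus_geometry(),
#'                         repair_parameters(), seed = 1)
#' @export
generate_uniform <- function(dose, phenotype, geometry, params, seed = NULL,
                             induction_time = 0, n_breaks = NULL,
                             chromosome_model = c("territory", "uniform")) {
  chromosome_model <- match.arg(chromosome_model)
  stopifnot(inherits(geometry, "nucleus_geometry"),
            inherits(phenotype, "radiation_phenotype"))
  if (dose < 0) abort("`dose` must be non-negative.")
  with_seed(seed, {
    n <- n_breaks %||%
      rpois(1, expected_dsb_count(dose, phenotype$genome_size,
                                  geometry$dsb_yield))
    if (n == 0) {
      return(new_damage_pattern(empty_breaks(), geometry, phenotype,
                                "uniform"))
    }
    pos <- runif_sphere(n, geometry$radius)
    chrom <- assign_chromosomes(n, phenotype, pos, geometry,
                                model = chromosome_model)
    new_damage_pattern(
      tibble(id = seq_len(n),
             x = pos[, "x"], y = pos[, "y"], z = pos[, "z"],
             chromosome = chrom$chromosome,
             genomic_coord = chrom$genomic_coord,
             complex = runif(n) < params$p_complex,
             induction_time = induction_time,
             track_id = -1L),
      geometry, phenotype, "uniform")
  })
}

#' Spread break inductions of a pattern over a protracted protocol
#'
#' Reassigns `induction_time` so that breaks arrive in proportion to the
#' delivered dose: impulse fractions contribute at their instant, finite
#' segments uniformly over their duration.
#'
#' @param pattern A `damage_pattern`.
#' @param protocol A [dose_protocol()].
#' @param seed RNG seed.
#' @return The pattern with updated induction times, sorted by time.
#' @export
schedule_inductions <- function(pattern, protocol, seed = NULL) {
  stopifnot(inherits(pattern, "damage_pattern"),
            inherits(protocol, "dose_protocol"))
  n <- nrow(pattern)
  if (n == 0) return(pattern)
  with_seed(seed, {
    seg <- sample.int(nrow(protocol), n, replace = TRUE,
                      prob = protocol$dose)
    t0 <- protocol$start[seg]
    dur <- protocol$duration[seg]
    tt <- t0 + runif(n) * dur
    pattern$induction_time <- tt
    out <- pattern[order(tt), ]
    out$id <- seq_len(n)
    out
  })
}

#' @export
print.damage_pattern <- function(x, ...) {
  g <- attr(x, "geometry")
  cat(sprintf("<damage_pattern> %d DSBs (%s) in R = %.3g um nucleus\n",
              nrow(x), attr(x, "provenance"), g$radius))
  NextMethod()
}
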