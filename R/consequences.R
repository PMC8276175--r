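#' Probability that a misrepair event is intra-chromosome
#'
#' Chromosomes are modelled as spherical territories of radius
#' `r_c = R / n_c^(1/3)` packed in the nucleus.  A misrepairing break end
#' sees its `1/n_c` same-chromosome partners at the (higher) mean
#' within-territory interaction rate `theta(r_c, sigma)` and the rest at
#' the nucleus-wide rate `theta(R, sigma)`, so the probability that the
#' interaction stays within one chromosome is
#' `theta(r_c, sigma) / (n_c * theta(R, sigma))`.
#'
#' @param geometry A [nucleus_geometry()].
#' @param sigma_abs Rejoining range in um.
#' @param n_chromosomes Chromosome count.
#' @return Probability in `[0, 1]`.
#' @examples
#' p_intra(nucleus_geometry(), 0.0418 * 4.23, 46)
#' @export
p_intra <- function(geometry, sigma_abs, n_chromosomes) {
  stopifnot(inherits(geometry, "nucleus_geometry"))
  if (n_chromosomes < 1) abort("`n_chromosomes` must be >= 1.")
  rc <- chromosome_radius(geometry, n_chromosomes)
  min(1, theta(rc, sigma_abs) / (n_chromosomes * theta(geometry$radius,
                                                       sigma_abs)))
}

#' Deletion-size distribution for intra-chromosome misrepair
#'
#' Genomic separation is assumed to grow monotonically with the spatial
#' separation of the break ends: `D = 2 L r^3 / R^3` MBP for ends `r`
#' apart (L the total genome length).  The probability that an
#' intra-chromosome misrepair produces a deletion smaller than `d` is the
#' fraction of within-territory interaction occurring below the matching
#' distance: `theta(r_c, sigma, r_d) / theta(r_c, sigma)` with
#' `r_d = R (d / 2L)^(1/3)`.
#'
#' @param d Deletion size in MBP (vector).
#' @param geometry A [nucleus_geometry()].
#' @param sigma_abs Rejoining range in um.
#' @param n_chromosomes Chromosome count.
#' @param genome_size Genome length in MBP.
#' @return `P(deletion < d)`, a valid CDF in `d`.
#' @export
deletion_size_cdf <- function(d, geometry, sigma_abs, n_chromosomes,
                              genome_size) {
  if (any(d < 0)) abort("`d` must be non-negative.")
  rc <- chromosome_radius(geometry, n_chromosomes)
  denom <- theta(rc, sigma_abs)
  r_d <- geometry$radius * (d / (2 * genome_size))^(1 / 3)
  vapply(r_d, function(r) theta(rc, sigma_abs, r) / denom, numeric(1))
}

# spatial separation corresponding to a genomic span (inverse size map)
span_to_distance <- function(d, geometry, genome_size) {
  geometry$radius * (d / (2 * genome_size))^(1 / 3)
}

distance_to_span <- function(r, geometry, genome_size) {
  2 * genome_size * r^3 / geometry$radius^3
}

# P(an intra-chromosome event of genomic span s crosses the centromere),
# with the centromere at fraction `centromere` of the chromosome and the
# span placed uniformly along it: min(1, s / (len - s)).
interarm_prob_given_span <- function(s, chrom_length, centromere = 0.5) {
  cl <- centromere * chrom_length
  lo <- pmax(0, pmin(cl, chrom_length - s) - pmax(0, cl - s))
  p <- ifelse(s >= chrom_length, 1, lo / pmax(chrom_length - s, 1e-300))
  pmin(1, pmax(0, p))
}

# Expectations over the within-territory interaction-distance density:
# E[f(span)] = int f(D(r)) dP(r) with dP from the truncated theta ratio.
expect_over_spans <- function(f, geometry, sigma_abs, n_chromosomes,
                              genome_size) {
  rc <- chromosome_radius(geometry, n_chromosomes)
  denom <- theta(rc, sigma_abs)
  if (denom <= 0) return(0)
  dens <- function(r) {
    zeta(r, sigma_abs) *
      (3 * r^2 / rc^3 - 9 * r^3 / (4 * rc^4) + 3 * r^5 / (16 * rc^6))
  }
  g <- function(r) {
    f(distance_to_span(r, geometry, genome_size)) * dens(r)
  }
  upper <- min(2 * rc, 12 * sigma_abs)  # zeta is zero beyond ~10 sigma
  integrate(g, 0, upper, rel.tol = 1e-8,
            subdivisions = 400L)$value / denom
}

#' Classify expected misrepair events into aberration types
#'
#' Misrepair events split into intra- and inter-chromosome interactions
#' by [p_intra()]; symmetric and asymmetric exchanges are equally likely.
#' Asymmetric inter-chromosome events are dicentrics; asymmetric
#' intra-chromosome events are deletions, whose sizes follow
#' [deletion_size_cdf()].  Inter-arm events (asymmetric intra-chromosome
#' events whose genomic span crosses the centromere, placed midway along
#' the chromosome by default) drive G2 lethality.
#'
#' @param n_mis Expected number of misrepair events (equal to misrepaired
#'   breaks).
#' @param geometry A [nucleus_geometry()].
#' @param sigma_abs Rejoining range in um.
#' @param phenotype A [radiation_phenotype()] (chromosome count, genome).
#' @param s_params A [survival_parameters()] (large-deletion threshold).
#' @param centromere Centromere position as a fraction of chromosome
#'   length.
#' @return An `aberration_counts` tibble (one row): `n_mis`, `p_intra`,
#'   `n_dicentric`, `n_deletion`, `n_deletion_large`, `n_interarm`,
#'   `n_symmetric`.
#' @examples
#' classify_misrepair(1, nucleus_geometry(), 0.0418 * 4.23,
#'                    radiation_phenotype(), survival_parameters())
#' @export
classify_misrepair <- function(n_mis, geometry, sigma_abs, phenotype,
                               s_params = survival_parameters(),
                               centromere = 0.5) {
  if (n_mis < 0) abort("`n_mis` must be non-negative.")
  n_c <- phenotype$n_chromosomes
  L <- phenotype$genome_size
  pint <- p_intra(geometry, sigma_abs, n_c)
  p_small <- deletion_size_cdf(s_params$large_deletion_threshold, geometry,
                               sigma_abs, n_c, L)
  chrom_len <- L / n_c
  p_interarm <- expect_over_spans(
    function(s) interarm_prob_given_span(s, chrom_len, centromere),
    geometry, sigma_abs, n_c, L)
  out <- tibble(
    n_mis = n_mis,
    p_intra = pint,
    n_dicentric = 0.5 * n_mis * (1 - pint),
    n_deletion = 0.5 * n_mis * pint,
    n_deletion_large = 0.5 * n_mis * pint * (1 - p_small),
    n_interarm = 0.5 * n_mis * pint * p_interarm,
    n_symmetric = 0.5 * n_mis
  )
  structure(out, class = c("aberration_counts", class(out)))
}

#' Classify Monte-Carlo repair events into aberration types
#'
#' Applies the same rules as [classify_misrepair()] to a concrete event
#' log: each misrepair event is inter- or intra-chromosome from its
#' recorded chromosome ids; the asymmetric/symmetric coin is flipped per
#' event; deletion sizes map from the spatial separation of the ends via
#' the global span-distance relation (for consistency with the analytic
#' model, which has no territory-resolved coordinates).
#'
#' @param log A [mc_repair()] event log.
#' @param geometry A [nucleus_geometry()].
#' @param phenotype A [radiation_phenotype()].
#' @param s_params A [survival_parameters()].
#' @param seed Seed for the symmetry coin flips.
#' @param centromere Centromere position fraction.
#' @return An `aberration_counts` tibble (one row), plus attribute
#'   `events`: the per-event classification.
#' @export
classify_events <- function(log, geometry, phenotype,
                            s_params = survival_parameters(), seed = NULL,
                            centromere = 0.5) {
  stopifnot(inherits(log, "repair_event_log"))
  mis <- log[!log$same_dsb, , drop = FALSE]
  if (nrow(mis) > 0 && (any(is.na(mis$chrom_a)) || any(is.na(mis$chrom_b)))) {
    abort("events lack chromosome annotations; cannot classify.")
  }
  n_mis <- nrow(mis)
  L <- phenotype$genome_size
  chrom_len <- L / phenotype$n_chromosomes
  if (n_mis == 0) {
    counts <- tibble(n_mis = 0, p_intra = NA_real_, n_dicentric = 0,
                     n_deletion = 0, n_deletion_large = 0, n_interarm = 0,
                     n_symmetric = 0)
    return(structure(counts, class = c("aberration_counts", class(counts)),
                     events = empty_event_rows()))
  }
  with_seed(seed, {
    asym <- runif(n_mis) < 0.5
    span <- distance_to_span(mis$distance, geometry, L)
    type <- ifelse(!asym, "symmetric",
                   ifelse(mis$inter_chromosome, "dicentric", "deletion"))
    # centromere crossing for asymmetric intra events: span placed
    # uniformly along the chromosome
    crosses <- rep(FALSE, n_mis)
    idx <- which(type == "deletion")
    if (length(idx) > 0) {
      s <- pmin(span[idx], chrom_len)
      start_max <- pmax(chrom_len - s, 1e-300)
      start <- runif(length(idx)) * start_max
      cl <- centromere * chrom_len
      crosses[idx] <- (start < cl) & (start + s > cl) | span[idx] >= chrom_len
    }
    counts <- tibble(
      n_mis = n_mis,
      p_intra = mean(!mis$inter_chromosome),
      n_dicentric = sum(type == "dicentric"),
      n_deletion = sum(type == "deletion"),
      n_deletion_large = sum(type == "deletion" &
                               span >= s_params$large_deletion_threshold),
      n_interarm = sum(crosses),
      n_symmetric = sum(type == "symmetric")
    )
    ev <- dplyr::mutate(mis, type = type, genomic_span_mapped = span,
                        crosses_centromere = crosses)
    structure(counts, class = c("aberration_counts", class(counts)),
              events = ev)
  })
}

#' Expected mutation yield in a gene of interest
#'
#' Structural mutations arise when a misrepair event's genomic span
#' overlaps the gene: for binary misrepair the span follows the
#' deletion-size distribution, so the overlap probability for a uniformly
#' placed gene of size `g` is `(E[span] + g) / L`; small-scale
#' (process-infidelity) misrepairs are treated as point-like
#' (`g / L`).  Correct repairs inside the gene mutate it with
#' probability `p_mut`.
#'
#' @param gene_size Gene size in MBP.
#' @param misrepair A `misrepair_summary` (from [misrepair_analytic()]).
#' @param geometry A [nucleus_geometry()].
#' @param phenotype A [radiation_phenotype()].
#' @param params A [repair_parameters()] (for `p_mut` and `sigma`).
#' @return A tibble: `gene_size`, `structural`, `point`, `total` expected
#'   mutations.
#' @export
mutation_rate <- function(gene_size, misrepair, geometry, phenotype,
                          params = repair_parameters()) {
  check_number(gene_size, "gene_size", min = 0)
  L <- phenotype$genome_size
  if (gene_size >= L / phenotype$n_chromosomes) {
    abort("`gene_size` must be smaller than a chromosome.")
  }
  sigma_abs <- params$sigma * geometry$radius
  mean_span <- expect_over_spans(identity, geometry, sigma_abs,
                                 phenotype$n_chromosomes, L)
  structural <- misrepair$n_mis_binary * (mean_span + gene_size) / L +
    misrepair$n_mis_process * gene_size / L
  point <- misrepair$n_correct * gene_size / L * params$p_mut
  tibble(gene_size = gene_size, structural = structural, point = point,
         total = structural + point)
}
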