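# Event-driven Monte Carlo repair engine.
#
# Every DSB contributes two free ends.  Each free end carries an
# exponential repair clock whose rate is the pathway rate scaled by the
# end's total interaction rate with all other free ends (Gaussian
# proximity weights; the correct partner contributes weight 1).  The end
# with the earliest clock initiates the next repair event and picks its
# partner with probability proportional to the pairwise weights.  Because
# the clocks are memoryless, re-sampling all affected clocks after every
# event is exact.

#' Per-end interaction and effective repair rates of a pattern
#'
#' For each break end, the total interaction rate with all other free
#' ends is `eta_i = 2 * sum_j zeta(r_ij) + 1` (two ends per partner
#' break, plus the correct partner at rate 1), and the effective repair
#' rate scales the pathway rate accordingly.  Per end, half the
#' per-break rate is used so that an isolated DSB rejoins at exactly its
#' pathway rate `lambda_x`.
#'
#' @param pattern A `damage_pattern`.
#' @param sigma_abs Rejoining range in um.
#' @return A tibble with one row per break: `eta_misrepair`
#'   (`2 sum_{j != i} zeta`), `eta_end` (including the correct partner)
#'   and nothing pathway-specific (rates attach in [mc_repair()]).
#' @export
mc_effective_rates <- function(pattern, sigma_abs) {
  stopifnot(inherits(pattern, "damage_pattern"))
  n <- nrow(pattern)
  if (n == 0) abort("empty pattern.")
  zmat <- zeta_matrix(pattern, sigma_abs)
  s <- unname(2 * (colSums(zmat) - 1))  # both ends of every other break
  tibble(id = pattern$id, eta_misrepair = s, eta_end = s + 1)
}

zeta_matrix <- function(pattern, sigma_abs) {
  pos <- as.matrix(pattern[, c("x", "y", "z")])
  d2 <- as.matrix(stats::dist(pos))^2
  z <- exp(-d2 / (2 * sigma_abs^2))
  diag(z) <- 1
  z
}

#' Simulate stochastic repair of a damage pattern
#'
#' Runs the event-driven rejoining simulation to completion and returns
#' the full repair-event log.  Pathways are drawn per break from the
#' class-conditional routing of `assignment` (using each break's
#' complexity flag); long-term-failure breaks are inert and never rejoin.
#' Breaks with `induction_time` in the future enter the simulation when
#' their time comes.
#'
#' @param pattern A `damage_pattern` (its `induction_time` column defines
#'   protracted delivery; see [schedule_inductions()]).
#' @param assignment A [assign_pathways()] result.
#' @param params A [repair_parameters()] (for `sigma`).
#' @param seed RNG seed; identical seed and inputs give an identical log.
#' @param sigma_abs Rejoining range in um (default `sigma * R`).
#' @return A `repair_event_log` tibble, one row per rejoining event:
#'   `time` (h), `dsb_a`, `dsb_b`, `same_dsb`, `pathway_a`, `pathway_b`,
#'   `chrom_a`, `chrom_b`, `coord_a`, `coord_b`, `inter_chromosome`,
#'   `genomic_span` (MBP, same-chromosome only), `distance` (um).
#'   Attributes carry the pattern, the per-break pathway draw and the ids
#'   of unrepaired breaks.
#' @export
mc_repair <- function(pattern, assignment, params = repair_parameters(),
                      seed = NULL, sigma_abs = NULL) {
  stopifnot(inherits(pattern, "damage_pattern"),
            inherits(assignment, "pathway_assignment"))
  geometry <- attr(pattern, "geometry")
  sigma_abs <- sigma_abs %||% (params$sigma * geometry$radius)
  n <- nrow(pattern)
  if (n == 0) {
    return(new_event_log(empty_event_rows(), pattern, character(0),
                         integer(0), seed))
  }
  with_seed(seed, {
    # per-break pathway draw from the class-conditional routing table,
    # with the long-term-failure fraction peeled off first
    routing <- assignment$routing
    flt <- assignment$long_term_failure_fraction
    cls <- ifelse(pattern$complex, "complex", "simple")
    pathway <- character(n)
    u_lt <- runif(n)
    for (i in seq_len(n)) {
      if (u_lt[i] < flt) {
        pathway[i] <- "fail"
      } else {
        pathway[i] <- sample(colnames(routing), 1,
                             prob = routing[cls[i], ])
      }
    }
    lam <- c(assignment$lambda, fail = 0)[match(pathway,
                                                c(names(assignment$lambda),
                                                  "fail"))]

    zmat <- zeta_matrix(pattern, sigma_abs)
    active <- pattern$induction_time <= min(pattern$induction_time)
    t_now <- min(pattern$induction_time)
    pending <- order(pattern$induction_time)
    pending <- pending[!active[pending]]

    free_ends <- ifelse(active, 2L, 0L)
    free_ends[pathway == "fail" & active] <- 0L  # inert
    # s[i] = sum over other breaks of free_ends * zeta
    live <- free_ends > 0
    s <- as.numeric(zmat %*% free_ends) - free_ends * 1

    ev_time <- numeric(n); ev_a <- integer(n); ev_b <- integer(n)
    n_events <- 0L

    # per-break clock rate: free ends each at half the per-break rate
    clock_rate <- function() {
      w <- s + (free_ends == 2L)          # partner available at zeta = 1
      free_ends * (lam / 2) * w
    }

    repeat {
      rates <- clock_rate()
      rates[free_ends == 0L] <- 0
      next_induction <- if (length(pending) > 0) {
        pattern$induction_time[pending[1]]
      } else {
        Inf
      }
      if (all(rates <= 0)) {
        t_event <- Inf
      } else {
        idx <- which(rates > 0)
        tt <- t_now + rexp(length(idx), rates[idx])
        j <- which.min(tt)
        t_event <- tt[j]
        i_event <- idx[j]
      }
      if (next_induction < t_event) {
        # activate every break induced at (essentially) this moment
        t_now <- next_induction
        batch <- pending[pattern$induction_time[pending] <= next_induction + 1e-12]
        pending <- setdiff(pending, batch)
        newly <- batch[pathway[batch] != "fail"]
        free_ends[newly] <- 2L
        if (length(newly) > 0) {
          s <- s + 2 * rowSums(zmat[, newly, drop = FALSE])
          s[newly] <- s[newly] - 2  # remove self contribution
          # recompute s for the new breaks against current occupancy
          s[newly] <- as.numeric(zmat[newly, , drop = FALSE] %*% free_ends) -
            free_ends[newly]
        }
        next
      }
      if (!is.finite(t_event)) break
      t_now <- t_event
      i <- i_event
      # partner weights: other breaks' free ends, plus own partner
      w <- free_ends * zmat[, i]
      w[i] <- if (free_ends[i] == 2L) 1 else 0
      k <- sample.int(n, 1, prob = w)
      n_events <- n_events + 1L
      ev_time[n_events] <- t_now
      ev_a[n_events] <- i
      ev_b[n_events] <- k
      if (k == i) {
        free_ends[i] <- 0L
        s <- s - 2 * zmat[, i]
        s[i] <- s[i] + 2
      } else {
        for (m in c(i, k)) {
          free_ends[m] <- free_ends[m] - 1L
          s <- s - zmat[, m]
          s[m] <- s[m] + 1
        }
      }
    }

    unrepaired <- which(free_ends > 0 | (pathway == "fail"))
    rows <- event_rows(pattern, pathway,
                       ev_time[seq_len(n_events)],
                       ev_a[seq_len(n_events)],
                       ev_b[seq_len(n_events)])
    new_event_log(rows, pattern, pathway, unrepaired, seed,
                  n_free_ends = sum(free_ends) + 2L * sum(pathway == "fail"))
  })
}

empty_event_rows <- function() {
  tibble(time = numeric(), dsb_a = integer(), dsb_b = integer(),
         same_dsb = logical(), pathway_a = character(),
         pathway_b = character(), chrom_a = integer(), chrom_b = integer(),
         coord_a = numeric(), coord_b = numeric(),
         inter_chromosome = logical(), genomic_span = numeric(),
         distance = numeric())
}

event_rows <- function(pattern, pathway, time, a, b) {
  if (length(time) == 0) return(empty_event_rows())
  same <- a == b
  inter <- pattern$chromosome[a] != pattern$chromosome[b]
  dx <- pattern$x[a] - pattern$x[b]
  dy <- pattern$y[a] - pattern$y[b]
  dz <- pattern$z[a] - pattern$z[b]
  tibble(
    time = time,
    dsb_a = pattern$id[a], dsb_b = pattern$id[b],
    same_dsb = same,
    pathway_a = pathway[a], pathway_b = pathway[b],
    chrom_a = pattern$chromosome[a], chrom_b = pattern$chromosome[b],
    coord_a = pattern$genomic_coord[a], coord_b = pattern$genomic_coord[b],
    inter_chromosome = inter,
    genomic_span = ifelse(!inter & !same,
                          abs(pattern$genomic_coord[a] -
                                pattern$genomic_coord[b]),
                          NA_real_),
    distance = sqrt(dx^2 + dy^2 + dz^2)
  )
}

new_event_log <- function(rows, pattern, pathway, unrepaired, seed,
                          n_free_ends = 0L) {
  structure(rows,
            class = c("repair_event_log", class(rows)),
            pattern = pattern,
            pathway = pathway,
            unrepaired = unrepaired,
            n_free_ends = n_free_ends,
            seed = seed)
}

#' Summarize a Monte-Carlo repair-event log
#'
#' Counts correct versus binary-misrepair events (misrepair events equal
#' misrepaired breaks: each incorrect event consumes one end from each of
#' two breaks), reconstructs the physical-break time course, and builds a
#' focus curve by adding an exponential protein-clearance delay (rate
#' `nu_x` of the initiating end's pathway) to every rejoining event.
#'
#' @param log A [mc_repair()] event log.
#' @param assignment The [assign_pathways()] result used for the run (for
#'   clearance rates).
#' @param times Time grid (h) for the kinetics curves.
#' @param seed Seed for the clearance-delay draws.
#' @return A list with `summary` (a `misrepair_summary`-like list of
#'   counts), and `kinetics`: a tibble `time`, `n_phys`, `n_foci`.
#' @export
mc_summary <- function(log, assignment, times = NULL, seed = NULL) {
  stopifnot(inherits(log, "repair_event_log"))
  pattern <- attr(log, "pattern")
  unrep <- attr(log, "unrepaired")
  n <- nrow(pattern)
  n_correct <- sum(log$same_dsb)
  n_mis <- sum(!log$same_dsb)
  n_unrepaired <- length(unrep)
  n_repaired <- n - n_unrepaired
  times <- times %||% c(0, 10^seq(-2, log10(48), length.out = 60))
  # physical breaks: each event removes two free ends = one DSB equivalent
  induced_at <- sort(pattern$induction_time)
  ev_t <- sort(log$time)
  n_phys <- sapply(times, function(t) {
    sum(induced_at <= t) - sum(ev_t <= t)
  })
  nu <- assignment$nu
  delays <- with_seed(seed, {
    rate <- nu[match(log$pathway_a, names(nu))]
    rate[is.na(rate)] <- nu[["slow"]]
    rexp(nrow(log), rate)
  })
  clear_t <- log$time + delays
  n_foci <- sapply(times, function(t) {
    sum(induced_at <= t) - sum(clear_t <= t)
  })
  list(
    summary = list(
      n_induced = n,
      n_repaired = n_repaired,
      n_unrepaired = n_unrepaired,
      n_correct = n_correct,
      n_mis = n_mis,
      p_correct = if (n_repaired > 0) n_correct / n_repaired else 1,
      misrepaired_fraction = if (n_repaired > 0) n_mis / n_repaired else 0
    ),
    kinetics = tibble(time = times, n_phys = n_phys, n_foci = n_foci)
  )
}
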