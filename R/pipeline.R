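# End-to-end orchestration: configuration files, the staged pipeline
# (initialize -> damage -> repair -> endpoints), result serialization and
# a reproducibility manifest.

config_schema <- list(
  phenotype = c("genome_size", "n_chromosomes", "nhej_competent",
                "hr_competent", "g1_arrest_competent", "cycle_phase",
                "phase_fractions", "long_term_failure_fraction"),
  repair_params = c("sigma", "mu_nhej", "mu_mmej", "p_mut", "p_complex",
                    "p_fail", "lambda_f", "lambda_s", "lambda_m", "nu_f",
                    "nu_s", "nu_m"),
  survival_params = c("phi", "psi_full", "psi_base",
                      "checkpoint_threshold", "large_deletion_threshold"),
  geometry = c("genome_size", "e_dsb", "dsb_yield", "radius"),
  protocol = c("segments", "acute_dose"),
  particle = c("species", "let", "profile_path", "core_radius", "r_max",
               "core_fraction"),
  run = c("seed", "doses", "times", "gene_size", "endpoints")
)

#' Read and validate a run configuration
#'
#' Configurations are YAML (or JSON) with the top-level blocks
#' `phenotype`, `repair_params`, `survival_params`, `geometry`,
#' `protocol`, `particle` and `run`; every key is optional and defaults
#' to the shipped model values.  Unknown keys are rejected by name.
#'
#' @param path Path to a YAML/JSON configuration file, or a list.
#' @return A validated config list with constructed model objects under
#'   `$objects`.
#' @export
read_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  cfg <- cfg %||% list()
  for (block in names(cfg)) {
    if (!block %in% names(config_schema)) {
      abort(sprintf("unknown config block `%s`.", block))
    }
    unknown <- setdiff(names(cfg[[block]]), config_schema[[block]])
    if (length(unknown) > 0) {
      abort(sprintf("unknown key `%s.%s` in configuration.",
                    block, unknown[1]))
    }
  }
  ph_args <- cfg$phenotype %||% list()
  if (!is.null(ph_args$phase_fractions)) {
    ph_args$phase_fractions <- unlist(ph_args$phase_fractions)
  }
  phenotype <- do.call(radiation_phenotype, ph_args)
  params <- do.call(repair_parameters, cfg$repair_params %||% list())
  s_params <- do.call(survival_parameters, cfg$survival_params %||% list())
  geo_args <- cfg$geometry %||% list()
  if (is.null(geo_args$genome_size)) {
    geo_args$genome_size <- phenotype$genome_size
  }
  geometry <- do.call(nucleus_geometry, geo_args)
  proto_cfg <- cfg$protocol %||% list(acute_dose = 1)
  protocol <- if (!is.null(proto_cfg$segments)) {
    dose_protocol(dplyr::bind_rows(lapply(proto_cfg$segments, as_tibble)))
  } else {
    acute_exposure(proto_cfg$acute_dose %||% 1)
  }
  profile <- NULL
  if (!is.null(cfg$particle)) {
    pc <- cfg$particle
    profile <- if (!is.null(pc$profile_path)) {
      read_track_profile(pc$profile_path, species = pc$species %||% "ion",
                         let = pc$let)
    } else {
      synthetic_track_profile(pc$let,
                              core_radius = pc$core_radius %||% 0.005,
                              r_max = pc$r_max %||% 0.5,
                              core_fraction = pc$core_fraction %||% 0.5,
                              species = pc$species %||% "ion")
    }
  }
  c(cfg, list(objects = list(phenotype = phenotype, params = params,
                             s_params = s_params, geometry = geometry,
                             protocol = protocol, profile = profile)))
}

#' Run the staged simulation pipeline
#'
#' Executes initialize -> damage -> repair -> endpoints for the requested
#' endpoint set and writes the results plus a run manifest (config
#' snapshot, seed, package version, output checksums) to `output_dir`.
#'
#' @param config A config path or list accepted by [read_config()].
#' @param output_dir Output directory (created if needed).
#' @param seed Overrides `run.seed` from the config.
#' @param endpoints Subset of `c("damage", "kinetics", "misrepair",
#'   "survival")`; defaults to the config's `run.endpoints` or all.
#' @return The manifest, invisibly; results are written as CSV/JSON.
#' @export
run_pipeline <- function(config, output_dir, seed = NULL,
                         endpoints = NULL) {
  cfg <- read_config(config)
  ob <- cfg$objects
  seed <- seed %||% cfg$run$seed %||% 1
  endpoints <- endpoints %||% cfg$run$endpoints %||%
    c("damage", "kinetics", "misrepair", "survival")
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  files <- character(0)
  log_stage <- function(fmt, ...) message(sprintf(fmt, ...))

  phase <- if (ob$phenotype$cycle_phase == "asynchronous") {
    resolve_phases(ob$phenotype)$phase[1]
  } else {
    ob$phenotype$cycle_phase
  }

  if ("damage" %in% endpoints) {
    pat <- if (is.null(ob$profile)) {
      generate_uniform(total_dose(ob$protocol), ob$phenotype, ob$geometry,
                       ob$params, seed = derive_seed(seed, 1))
    } else {
      generate_track_pattern(total_dose(ob$protocol), ob$profile,
                             ob$phenotype, ob$geometry, ob$params,
                             seed = derive_seed(seed, 1))
    }
    log_stage("damage: %d DSBs induced", nrow(pat))
    f <- file.path(output_dir, "damage.sdd")
    write_sdd(sdd_from_pattern(pat, dose = total_dose(ob$protocol)), f)
    files <- c(files, f)
  }

  if ("kinetics" %in% endpoints) {
    kin <- repair_kinetics(ob$protocol, ob$phenotype, ob$geometry,
                           ob$params, phase = phase,
                           times = cfg$run$times)
    log_stage("kinetics: %d time points", nrow(kin))
    f <- file.path(output_dir, "kinetics.csv")
    readr_write(kin, f)
    files <- c(files, f)
  }

  mis <- NULL
  if (any(c("misrepair", "survival") %in% endpoints)) {
    eta_tr <- if (is.null(ob$profile)) 0 else {
      eta_track(ob$profile, ob$geometry,
                ob$params$sigma * ob$geometry$radius,
                seed = derive_seed(seed, 2))
    }
    mis <- misrepair_analytic(ob$protocol, ob$phenotype, ob$geometry,
                              ob$params, phase = phase,
                              eta_track_value = eta_tr)
    log_stage("misrepair: %.3g of %.3g breaks misrepaired",
              mis$n_mis, mis$n_induced)
  }
  if ("misrepair" %in% endpoints) {
    f <- file.path(output_dir, "misrepair.json")
    jsonlite::write_json(mis[c("n_induced", "n_repaired", "n_unrepaired",
                               "n_correct", "n_mis", "n_mis_binary",
                               "n_mis_process", "p_correct", "eta_prime",
                               "eta_track")],
                         f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
    if (!is.null(cfg$run$gene_size)) {
      mut <- mutation_rate(cfg$run$gene_size, mis, ob$geometry,
                           ob$phenotype, ob$params)
      f <- file.path(output_dir, "mutation.csv")
      readr_write(mut, f)
      files <- c(files, f)
    }
  }

  if ("survival" %in% endpoints) {
    doses <- cfg$run$doses %||% c(0, 1, 2, 4, 6, 8)
    dr <- dose_response(unlist(doses), ob$phenotype, ob$geometry,
                        ob$params, ob$s_params, profile = ob$profile)
    log_stage("survival: %d dose points, S(max dose) = %.3g",
              nrow(dr), min(dr$s_total))
    f <- file.path(output_dir, "survival.csv")
    readr_write(dplyr::rename(as_tibble(dr), dose_Gy = "dose_gy"), f)
    files <- c(files, f)
    lq <- tryCatch(fit_lq(dr), error = function(e) NULL)
    summ <- list(mid_gy = mid(dr, n_grid = 24),
                 alpha = lq$alpha, beta = lq$beta)
    f <- file.path(output_dir, "survival_summary.json")
    jsonlite::write_json(summ, f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
  }

  manifest <- list(
    package_version = as.character(packageVersion("medras")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = seed,
    config = cfg[setdiff(names(cfg), "objects")],
    outputs = lapply(files, function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  mf <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

readr_write <- function(df, path) {
  write.csv(as.data.frame(df), path, row.names = FALSE)
  path
}

#' Serialize a result set
#'
#' @param results Named list of data frames / lists.
#' @param format `"json"`, `"csv"` or `"markdown"`.
#' @param dir Output directory.
#' @return Character vector of written files.
#' @export
report <- function(results, format = c("json", "csv", "markdown"),
                   dir = ".") {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- character(0)
  for (nm in names(results)) {
    x <- results[[nm]]
    f <- switch(format,
      json = {
        p <- file.path(dir, paste0(nm, ".json"))
        jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA)
        p
      },
      csv = {
        p <- file.path(dir, paste0(nm, ".csv"))
        readr_write(as.data.frame(x), p)
        p
      },
      markdown = {
        p <- file.path(dir, paste0(nm, ".md"))
        df <- as.data.frame(x)
        hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
        sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
        rows <- apply(df, 1, function(r) {
          paste0("| ", paste(format(r, digits = 6), collapse = " | "), " |")
        })
        writeLines(c(paste0("## ", nm), "", hdr, sep, rows), p)
        p
      })
    out <- c(out, f)
  }
  out
}
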