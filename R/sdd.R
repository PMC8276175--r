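# Plain-text interchange of damage patterns in a minimal dialect of the
# Standard for DNA Damage (SDD) format: a header of "Key, value;" lines
# terminated by ***EndOfHeader***, followed by one record per break with
# semicolon-separated fields.  Supported record fields, in order:
#   1  classification: "<new_exposure_flag>, <track_id>"
#   2  position:       "<x>, <y>, <z>"            (um)
#   3  chromosome id:  "<chromosome>"
#   4  genomic coord:  "<MBP along the chromosome>"
#   5  damage class:   "<0|1>"                    (complex flag)
#   6  time:           "<induction time, h>"
# Unknown additional fields are preserved verbatim on round-trip.

SDD_VERSION <- "1.0"

#' Construct / inspect an SDD document
#'
#' An `sdd_document` couples an ordered header (named character vector)
#' with a tibble of damage records.  [read_sdd()] and [write_sdd()]
#' round-trip all supported fields exactly; unknown record fields survive
#' in the `extra` column.
#'
#' @param header Named character vector of header metadata.  A
#'   `"SDD version"` entry is added when absent.
#' @param records Tibble with columns `new_exposure`, `track_id`, `x`,
#'   `y`, `z`, `chromosome`, `genomic_coord`, `complex`, `time` and
#'   optionally `extra`.
#' @return An object of class `sdd_document`.
#' @export
sdd_document <- function(header, records) {
  if (is.null(names(header)) || any(!nzchar(names(header)))) {
    abort("`header` must be a fully named character vector.")
  }
  header <- vapply(header, as.character, character(1))
  if (!"SDD version" %in% names(header)) {
    header <- c("SDD version" = SDD_VERSION, header)
  }
  records <- as_tibble(records)
  req <- c("new_exposure", "track_id", "x", "y", "z", "chromosome",
           "genomic_coord", "complex", "time")
  missing <- setdiff(req, names(records))
  if (length(missing) > 0) {
    abort(sprintf("records lack field(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  if (!"extra" %in% names(records)) records$extra <- ""
  structure(list(header = header, records = records),
            class = "sdd_document")
}

#' @export
print.sdd_document <- function(x, ...) {
  cat(sprintf("<sdd_document> v%s, %d records, %d header entries\n",
              x$header[["SDD version"]], nrow(x$records),
              length(x$header)))
  invisible(x)
}

#' Write an SDD document (or damage pattern) to a file
#'
#' @param doc An [sdd_document()] or a `damage_pattern` (converted with
#'   [sdd_from_pattern()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sdd <- function(doc, path) {
  if (inherits(doc, "damage_pattern")) doc <- sdd_from_pattern(doc)
  stopifnot(inherits(doc, "sdd_document"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(doc$header)) {
    writeLines(sprintf("%s, %s;", names(doc$header)[i], doc$header[[i]]),
               con)
  }
  writeLines("***EndOfHeader***;", con)
  r <- doc$records
  num <- function(x) formatC(x, digits = 10, format = "g")
  lines <- sprintf("%d, %d; %s, %s, %s; %d; %s; %d; %s;%s",
                   r$new_exposure, r$track_id,
                   num(r$x), num(r$y), num(r$z),
                   r$chromosome, num(r$genomic_coord),
                   as.integer(r$complex), num(r$time),
                   ifelse(nzchar(r$extra), paste0(" ", r$extra, ";"), ""))
  writeLines(lines, con)
  invisible(path)
}

#' Read an SDD file
#'
#' @param path File path.
#' @return An [sdd_document()].
#' @export
read_sdd <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  end_hdr <- grep("^\\*\\*\\*EndOfHeader\\*\\*\\*", lines)
  if (length(end_hdr) == 0) {
    abort("malformed SDD file: missing ***EndOfHeader*** terminator.")
  }
  end_hdr <- end_hdr[1]
  hdr_lines <- lines[seq_len(end_hdr - 1)]
  hdr_lines <- hdr_lines[nzchar(trimws(hdr_lines))]
  kv <- regmatches(hdr_lines, regexec("^([^,]+),\\s*(.*?);?\\s*$",
                                      hdr_lines))
  bad <- which(vapply(kv, length, integer(1)) != 3)
  if (length(bad) > 0) {
    abort(sprintf("malformed SDD header at line %d.", bad[1]))
  }
  header <- setNames(vapply(kv, `[`, character(1), 3),
                     trimws(vapply(kv, `[`, character(1), 2)))
  if (!"SDD version" %in% names(header)) {
    abort("SDD header lacks an 'SDD version' entry.")
  }
  if (!startsWith(trimws(header[["SDD version"]]), "1.")) {
    abort(sprintf("unsupported SDD version '%s'.",
                  header[["SDD version"]]))
  }
  data_lines <- lines[-seq_len(end_hdr)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  parse_line <- function(ln, lineno) {
    fields <- trimws(strsplit(ln, ";")[[1]])
    fields <- fields[nzchar(fields) | seq_along(fields) <= 6]
    if (length(fields) < 6) {
      abort(sprintf("malformed SDD record at line %d: expected 6 fields, got %d.",
                    lineno, length(fields)))
    }
    cls <- as.numeric(strsplit(fields[1], ",")[[1]])
    pos <- as.numeric(strsplit(fields[2], ",")[[1]])
    if (length(cls) != 2 || anyNA(cls) || length(pos) != 3 || anyNA(pos)) {
      abort(sprintf("malformed SDD record at line %d.", lineno))
    }
    chrom <- as.integer(fields[3])
    coord <- as.numeric(fields[4])
    cmplx <- as.integer(fields[5])
    tt <- as.numeric(fields[6])
    if (anyNA(c(chrom, coord, cmplx, tt))) {
      abort(sprintf("malformed SDD record at line %d.", lineno))
    }
    extra <- if (length(fields) > 6) {
      paste(fields[7:length(fields)], collapse = "; ")
    } else {
      ""
    }
    tibble(new_exposure = as.integer(cls[1]), track_id = as.integer(cls[2]),
           x = pos[1], y = pos[2], z = pos[3],
           chromosome = chrom, genomic_coord = coord,
           complex = cmplx == 1L, time = tt, extra = extra)
  }
  records <- if (length(data_lines) == 0) {
    tibble(new_exposure = integer(), track_id = integer(), x = numeric(),
           y = numeric(), z = numeric(), chromosome = integer(),
           genomic_coord = numeric(), complex = logical(),
           time = numeric(), extra = character())
  } else {
    dplyr::bind_rows(Map(parse_line, data_lines,
                         end_hdr + seq_along(data_lines)))
  }
  sdd_document(header, records)
}

#' Convert between SDD documents and damage patterns
#'
#' `pattern_from_sdd()` maps SDD records onto a `damage_pattern`; the
#' complexity flag is taken from the file.  `sdd_from_pattern()` is the
#' inverse, stamping geometry and provenance into the header.
#'
#' @param doc An [sdd_document()].
#' @param geometry A [nucleus_geometry()]; when `NULL`, reconstructed
#'   from the header where possible.
#' @param phenotype A [radiation_phenotype()].
#' @return A `damage_pattern` / an `sdd_document`.
#' @export
pattern_from_sdd <- function(doc, geometry = NULL,
                             phenotype = radiation_phenotype()) {
  stopifnot(inherits(doc, "sdd_document"))
  if (is.null(geometry)) {
    r_hdr <- suppressWarnings(as.numeric(doc$header["Nucleus radius"]))
    geometry <- if (is.finite(r_hdr)) {
      nucleus_geometry(genome_size = phenotype$genome_size, radius = r_hdr)
    } else {
      nucleus_geometry(genome_size = phenotype$genome_size)
    }
  }
  r <- doc$records
  new_damage_pattern(
    tibble(id = seq_len(nrow(r)),
           x = r$x, y = r$y, z = r$z,
           chromosome = r$chromosome,
           genomic_coord = r$genomic_coord,
           complex = r$complex,
           induction_time = r$time,
           track_id = r$track_id),
    geometry, phenotype, "sdd")
}

#' @rdname pattern_from_sdd
#' @param pattern A `damage_pattern`.
#' @param dose Dose (Gy) recorded in the header, if known.
#' @export
sdd_from_pattern <- function(pattern, dose = NA) {
  stopifnot(inherits(pattern, "damage_pattern"))
  geometry <- attr(pattern, "geometry")
  header <- c(
    "SDD version" = SDD_VERSION,
    "Software" = paste0("medras ", as.character(packageVersion("medras"))),
    "Data entries" = "classification, position, chromosome, genomic coordinate, damage class, time",
    "Dose or fluence" = paste0("1, ", ifelse(is.na(dose), 0, dose)),
    "Nucleus radius" = formatC(geometry$radius, digits = 10, format = "g"),
    "Damage definition" = "DSB",
    "Provenance" = as.character(attr(pattern, "provenance"))
  )
  n <- nrow(pattern)
  sdd_document(header, tibble(
    new_exposure = if (n == 0) integer() else c(2L, rep(0L, n - 1)),
    track_id = pattern$track_id,
    x = pattern$x, y = pattern$y, z = pattern$z,
    chromosome = pattern$chromosome,
    genomic_coord = pattern$genomic_coord,
    complex = pattern$complex,
    time = pattern$induction_time))
}
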