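#' Construct a caudal series
#'
#' A `caudal_series` holds one specimen's ordered per-vertebra centrum
#' lengths. Vertebra numbering is 1-based with caudal 1 the first vertebra
#' behind the sacrum; missing vertebrae appear as gaps in `positions`, never
#' as zero lengths. The optional transition point is the number of the last
#' vertebra bearing lateral (transverse) processes.
#'
#' @param specimen_id Character scalar, unique specimen identifier.
#' @param taxon Character scalar.
#' @param positions Integer vector of vertebra numbers, strictly increasing.
#' @param lengths Numeric vector of centrum lengths in mm, parallel to
#'   `positions`; all finite and positive.
#' @param clade Optional character scalar.
#' @param transition_point Optional vertebra number of the last centrum with a
#'   lateral process; must lie within `range(positions)` when present.
#' @param complete Logical completeness status of the tail (may be `NA`).
#' @return An object of class `caudal_series`.
#' @examples
#' caudal_series("X1", "Examplesaurus", 1:10, seq(30, 12, length.out = 10))
#' @export
caudal_series <- function(specimen_id, taxon, positions, lengths,
                          clade = NA_character_, transition_point = NA_real_,
                          complete = NA) {
  positions <- as.numeric(positions)
  lengths <- as.numeric(lengths)
  if (length(positions) != length(lengths)) {
    stop_caudseg("positions and lengths must have equal length",
                 "caudseg_validation_error")
  }
  if (anyNA(positions) || any(diff(positions) <= 0)) {
    stop_caudseg(sprintf("positions for specimen '%s' must be strictly increasing",
                         specimen_id), "caudseg_validation_error")
  }
  if (any(positions != round(positions)) || any(positions < 1)) {
    stop_caudseg("positions must be 1-based integers", "caudseg_validation_error")
  }
  if (anyNA(lengths) || any(!is.finite(lengths)) || any(lengths <= 0)) {
    bad <- which(!is.finite(lengths) | lengths <= 0)
    stop_caudseg(sprintf("non-positive or non-finite centrum length for specimen '%s' at positions %s",
                         specimen_id, paste(positions[bad], collapse = ", ")),
                 "caudseg_validation_error")
  }
  if (!is.na(transition_point) &&
      (transition_point < min(positions) || transition_point > max(positions))) {
    stop_caudseg(sprintf("transition_point %s outside position range for specimen '%s'",
                         format(transition_point), specimen_id),
                 "caudseg_validation_error")
  }
  structure(list(
    specimen_id = as.character(specimen_id),
    taxon = as.character(taxon),
    clade = as.character(clade),
    positions = positions,
    lengths = lengths,
    transition_point = as.numeric(transition_point),
    complete = as.logical(complete)
  ), class = "caudal_series")
}

#' @export
print.caudal_series <- function(x, ...) {
  cat(sprintf("<caudal_series> %s (%s)\n", x$specimen_id, x$taxon))
  cat(sprintf("  %d vertebrae, positions %d..%d%s\n", length(x$positions),
              min(x$positions), max(x$positions),
              if (length(x$positions) < max(x$positions) - min(x$positions) + 1)
                " (with gaps)" else ""))
  cat(sprintf("  centrum length %.1f..%.1f mm\n", min(x$lengths), max(x$lengths)))
  if (!is.na(x$transition_point))
    cat(sprintf("  transition point at vertebra %s\n", format(x$transition_point)))
  invisible(x)
}

#' @export
format.caudal_series <- function(x, ...) {
  sprintf("caudal_series(%s, n=%d)", x$specimen_id, length(x$positions))
}

# columns of the canonical long-format series CSV
.series_cols_required <- c("specimen_id", "taxon", "vertebra_number",
                           "centrum_length_mm")

# header synonyms accepted by the master-layout adapter (lower-cased,
# punctuation stripped)
.series_header_map <- c(
  specimen = "specimen_id", specimenid = "specimen_id",
  specimennumber = "specimen_id", id = "specimen_id",
  taxon = "taxon", species = "taxon", genus = "taxon",
  clade = "clade", group = "clade",
  vertebra = "vertebra_number", vertebranumber = "vertebra_number",
  caudal = "vertebra_number", caudalnumber = "vertebra_number",
  position = "vertebra_number",
  centrumlength = "centrum_length_mm", centrumlengthmm = "centrum_length_mm",
  length = "centrum_length_mm", lengthmm = "centrum_length_mm",
  lateralprocess = "has_lateral_process", transverseprocess = "has_lateral_process",
  haslateralprocess = "has_lateral_process"
)

.normalise_headers <- function(nms) {
  key <- gsub("[^a-z]", "", tolower(nms))
  mapped <- .series_header_map[key]
  ifelse(is.na(mapped), nms, mapped)
}

.as_flag <- function(v) {
  if (is.logical(v)) return(v)
  if (is.numeric(v)) return(v != 0)
  s <- tolower(trimws(as.character(v)))
  out <- rep(NA, length(s))
  out[s %in% c("true", "t", "yes", "y", "1")] <- TRUE
  out[s %in% c("false", "f", "no", "n", "0", "")] <- FALSE
  out
}

#' Read a long-format table of per-vertebra measurements
#'
#' Reads the canonical series CSV (columns `specimen_id`, `taxon`,
#' `vertebra_number`, `centrum_length_mm`, optional `clade` and
#' `has_lateral_process`) and returns one [caudal_series] per specimen.
#' Rows with a missing centrum length are dropped, producing position gaps;
#' the number dropped is reported via `message()`. The transition point is
#' derived as the largest vertebra number whose `has_lateral_process` flag is
#' true, and is absent when the flag column is absent.
#'
#' `format = "master"` is a thin adapter for CSV exports of the deposited
#' master-dataset spreadsheet layout: column headers are matched
#' case-insensitively against common synonyms (e.g. `Vertebra`, `Length (mm)`,
#' `Lateral process`) and mapped onto the canonical schema.
#'
#' @param path Path to a CSV file.
#' @param format `"csv"` (canonical schema) or `"master"` (tolerant
#'   header-mapping adapter for spreadsheet exports).
#' @return A named list of [caudal_series], in order of first appearance.
#' @seealso [write_series_table()]
#' @export
read_series_table <- function(path, format = c("csv", "master")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_caudseg(sprintf("file not found: %s", path), "caudseg_io_error")
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (format == "master") names(df) <- .normalise_headers(names(df))
  missing_cols <- setdiff(.series_cols_required, names(df))
  if (length(missing_cols)) {
    stop_caudseg(sprintf("missing required column(s): %s",
                         paste(missing_cols, collapse = ", ")),
                 "caudseg_schema_error")
  }
  if (!"clade" %in% names(df)) df$clade <- NA_character_
  has_flag <- "has_lateral_process" %in% names(df)

  len <- suppressWarnings(as.numeric(df$centrum_length_mm))
  drop <- is.na(df$centrum_length_mm) | trimws(as.character(df$centrum_length_mm)) == ""
  bad <- which(!drop & (is.na(len) | len <= 0))
  if (length(bad)) {
    stop_caudseg(sprintf("non-positive or non-numeric centrum_length_mm in row(s): %s",
                         paste(bad, collapse = ", ")),
                 "caudseg_validation_error")
  }
  if (any(drop)) {
    message(sprintf("read_series_table: dropped %d row(s) with missing centrum length",
                    sum(drop)))
    df <- df[!drop, , drop = FALSE]
    len <- len[!drop]
  }
  df$centrum_length_mm <- len

  dup <- duplicated(df[c("specimen_id", "vertebra_number")])
  if (any(dup)) {
    stop_caudseg(sprintf("duplicated (specimen, vertebra) pair(s): %s",
                         paste(unique(sprintf("(%s, %s)", df$specimen_id[dup],
                                              df$vertebra_number[dup])),
                               collapse = ", ")),
                 "caudseg_validation_error")
  }

  ids <- unique(df$specimen_id)
  out <- lapply(ids, function(id) {
    sub <- df[df$specimen_id == id, , drop = FALSE]
    sub <- sub[order(sub$vertebra_number), , drop = FALSE]
    tp <- NA_real_
    if (has_flag) {
      fl <- .as_flag(sub$has_lateral_process)
      if (any(fl %in% TRUE)) tp <- max(sub$vertebra_number[fl %in% TRUE])
    }
    caudal_series(
      specimen_id = id,
      taxon = sub$taxon[1],
      clade = sub$clade[1],
      positions = sub$vertebra_number,
      lengths = sub$centrum_length_mm,
      transition_point = tp,
      complete = NA
    )
  })
  names(out) <- ids
  out
}

#' Write caudal series to the canonical CSV schema
#'
#' Inverse of [read_series_table()]: `read_series_table(write_series_table(x))`
#' reproduces the input field-for-field (position gaps included). An empty
#' list yields a header-only file.
#'
#' @param series A list of [caudal_series].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_series_table <- function(series, path) {
  stopifnot(is.list(series))
  rows <- lapply(series, function(s) {
    stopifnot(inherits(s, "caudal_series"))
    flag <- if (is.na(s$transition_point)) NA else s$positions <= s$transition_point
    data.frame(
      specimen_id = s$specimen_id, taxon = s$taxon, clade = s$clade,
      vertebra_number = s$positions, centrum_length_mm = s$lengths,
      has_lateral_process = flag, stringsAsFactors = FALSE
    )
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(specimen_id = character(), taxon = character(),
               clade = character(), vertebra_number = numeric(),
               centrum_length_mm = numeric(), has_lateral_process = logical())
  # drop the flag column entirely when no specimen carries a transition point,
  # so that absence of the column round-trips to absence of the field
  if (nrow(df) && all(is.na(df$has_lateral_process))) df$has_lateral_process <- NULL
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

.locomotor_classes <- c("biped", "quadruped", "facultative_biped")

#' Read a per-specimen measurement table
#'
#' Reads `specimens.csv` (columns `specimen_id`, `taxon`, `femur_mm`; optional
#' `snout_sacrum_mm`, `tail_mm`, `locomotor_class`, `largest_of_species`) into
#' a validated data frame with one row per specimen. All lengths are in mm and
#' must be positive where present; `locomotor_class` must be one of `"biped"`,
#' `"quadruped"`, `"facultative_biped"` (or missing); `largest_of_species`
#' defaults to `FALSE` when the column is absent.
#'
#' @param path Path to a CSV file.
#' @return A `data.frame` with class `specimen_table`.
#' @export
read_specimen_table <- function(path) {
  if (!file.exists(path)) {
    stop_caudseg(sprintf("file not found: %s", path), "caudseg_io_error")
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("specimen_id", "taxon", "femur_mm")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_caudseg(sprintf("missing required column(s): %s",
                         paste(missing_cols, collapse = ", ")),
                 "caudseg_schema_error")
  }
  for (col in c("snout_sacrum_mm", "tail_mm")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  if (!"locomotor_class" %in% names(df)) df$locomotor_class <- NA_character_
  if (!"largest_of_species" %in% names(df)) df$largest_of_species <- FALSE
  df$largest_of_species <- .as_flag(df$largest_of_species) %in% TRUE
  df$femur_mm <- suppressWarnings(as.numeric(df$femur_mm))

  for (col in c("femur_mm", "snout_sacrum_mm", "tail_mm")) {
    bad <- which(!is.na(df[[col]]) & df[[col]] <= 0)
    if (length(bad)) {
      stop_caudseg(sprintf("non-positive %s in row(s): %s", col,
                           paste(bad, collapse = ", ")),
                   "caudseg_validation_error")
    }
  }
  lc <- trimws(df$locomotor_class)
  lc[lc == ""] <- NA_character_
  unknown <- setdiff(unique(lc[!is.na(lc)]), .locomotor_classes)
  if (length(unknown)) {
    stop_caudseg(sprintf("unknown locomotor_class value(s): %s (expected %s)",
                         paste(unknown, collapse = ", "),
                         paste(.locomotor_classes, collapse = "/")),
                 "caudseg_validation_error")
  }
  df$locomotor_class <- lc
  if (anyDuplicated(df$specimen_id)) {
    stop_caudseg("duplicated specimen_id in specimen table",
                 "caudseg_validation_error")
  }
  class(df) <- c("specimen_table", "data.frame")
  df
}
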