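# Reading, validating and writing HuskinDB-style tables.
#
# Conventions: log Kp is log10 of the permeability coefficient with Kp in
# cm/s, exactly as the database exports it; no unit conversion happens
# anywhere in the package. Missing values are an empty cell or "NA" on
# read and are written back as empty cells.

permeability_columns <- function() {
  c("compound_id", "compound_name", "log_kp_cm_s", "skin_source",
    "skin_layer", "donor_concentration", "donor_temperature_c", "donor_ph")
}

# compound_name and donor_ph are informational; everything else must exist
required_permeability_columns <- function() {
  setdiff(permeability_columns(), c("compound_name", "donor_ph"))
}

infer_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.tsv$|\\.tab$", path, ignore.case = TRUE)) "\t" else ","
}

read_delim_checked <- function(path, sep) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, colClasses = "character",
                    check.names = FALSE, na.strings = NULL,
                    comment.char = "")
}

apply_col_map <- function(df, col_map) {
  if (is.null(col_map)) return(df)
  stopifnot(is.character(col_map), !is.null(names(col_map)))
  for (canon in names(col_map)) {
    raw <- col_map[[canon]]
    if (raw %in% names(df)) names(df)[names(df) == raw] <- canon
  }
  df
}

parse_numeric_column <- function(x, column, required = FALSE) {
  x <- trimws(x)
  blank <- is_blank(x) | toupper(x) == "NA"
  out <- suppressWarnings(as.numeric(x))
  bad <- !blank & is.na(out)
  if (any(bad)) {
    stop(sprintf("non-numeric %s at row(s) %s", column,
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  }
  if (required && any(blank)) {
    stop(sprintf("missing %s at row(s) %s", column,
                 paste(which(blank), collapse = ", ")), call. = FALSE)
  }
  out[blank] <- NA_real_
  out
}

#' Read a HuskinDB-style permeability table
#'
#' Reads a delimited text table with one row per Kp measurement. Required
#' columns (renameable through `col_map`): `compound_id`, `log_kp_cm_s`,
#' `skin_source`, `skin_layer`, `donor_concentration`,
#' `donor_temperature_c`; optional: `compound_name`, `donor_ph`.
#' Categorical values are normalized onto the controlled vocabularies
#' (see [skin_sources()] and friends); unrecognized values are mapped to
#' missing with a single summarizing warning and counted in the
#' `"n_unparseable"` attribute. Row order is preserved.
#'
#' `log_kp_cm_s` is log10 of the permeability coefficient in cm/s. Values
#' outside the plausible range \[-9, -2\] raise a warning but are kept.
#'
#' @param path Path to a CSV (default) or TSV file with a header row.
#' @param sep Field separator; by default inferred from the file
#'   extension (`.tsv`/`.tab` means tab, otherwise comma).
#' @param col_map Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(log_kp_cm_s = "logKp")`.
#' @return A data frame of permeability records with the canonical
#'   columns, one row per measurement.
#' @seealso [write_permeability_table()], [filter_complete()]
#' @export
read_permeability_table <- function(path, sep = NULL, col_map = NULL) {
  df <- read_delim_checked(path, infer_sep(path, sep))
  df <- apply_col_map(df, col_map)
  missing_cols <- setdiff(required_permeability_columns(), names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"compound_name" %in% names(df)) df$compound_name <- NA_character_
  if (!"donor_ph" %in% names(df)) df$donor_ph <- ""

  n <- nrow(df)
  out <- data.frame(
    compound_id = trimws(df$compound_id),
    compound_name = ifelse(is_blank(df$compound_name) |
                             toupper(trimws(df$compound_name)) == "NA",
                           NA_character_, trimws(df$compound_name)),
    log_kp = parse_numeric_column(df$log_kp_cm_s, "log_kp_cm_s",
                                  required = TRUE),
    stringsAsFactors = FALSE
  )
  raw_source <- df$skin_source
  raw_layer <- df$skin_layer
  raw_conc <- df$donor_concentration
  out$skin_source <- normalize_skin_source(raw_source)
  out$skin_layer <- normalize_skin_layer(raw_layer)
  out$donor_concentration <- normalize_donor_concentration(raw_conc)
  out$donor_temperature_c <- parse_numeric_column(df$donor_temperature_c,
                                                  "donor_temperature_c")
  out$donor_ph <- parse_numeric_column(df$donor_ph, "donor_ph")

  # values present in the file but outside the vocabulary
  n_unparseable <-
    sum(is.na(out$skin_source) & !is_blank(raw_source) &
          toupper(trimws(raw_source)) != "NA") +
    sum(is.na(out$skin_layer) & !is_blank(raw_layer) &
          toupper(trimws(raw_layer)) != "NA") +
    sum(is.na(out$donor_concentration) & !is_blank(raw_conc) &
          toupper(trimws(raw_conc)) != "NA")
  if (n_unparseable > 0) {
    warning(sprintf(
      "%d categorical value(s) outside the controlled vocabulary mapped to missing",
      n_unparseable), call. = FALSE)
  }
  out_of_range <- !is.na(out$log_kp) & (out$log_kp < -9 | out$log_kp > -2)
  if (any(out_of_range)) {
    warning(sprintf(
      "%d log Kp value(s) outside the typical range [-9, -2] (kept)",
      sum(out_of_range)), call. = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "n_unparseable") <- as.integer(n_unparseable)
  out
}

#' Write a permeability table
#'
#' Inverse of [read_permeability_table()]: writes the canonical columns as
#' delimited text with missing values as empty cells, so a write/read
#' round trip reproduces every field.
#'
#' @param records Data frame of permeability records.
#' @param path Output path.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_permeability_table <- function(records, path, sep = ",") {
  df <- data.frame(
    compound_id = records$compound_id,
    compound_name = records$compound_name,
    log_kp_cm_s = records$log_kp,
    skin_source = records$skin_source,
    skin_layer = records$skin_layer,
    donor_concentration = records$donor_concentration,
    donor_temperature_c = records$donor_temperature_c,
    donor_ph = records$donor_ph,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Read a molecular descriptor table
#'
#' Reads a delimited table with columns `compound_id`, `logp` (octanol-
#' water partition coefficient), `tpsa` (topological polar surface area,
#' square Angstrom) and `mv` (molecular volume, cubic Angstrom); column
#' matching is case-insensitive. Each compound may appear only once.
#'
#' @param path Path to a CSV/TSV file with a header.
#' @param sep Field separator; inferred from the extension by default.
#' @return A data frame with one row per compound, keyed by
#'   `compound_id`.
#' @export
read_descriptor_table <- function(path, sep = NULL) {
  df <- read_delim_checked(path, infer_sep(path, sep))
  names(df) <- tolower(names(df))
  missing_cols <- setdiff(c("compound_id", "logp", "tpsa", "mv"), names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(
    compound_id = trimws(df$compound_id),
    logp = parse_numeric_column(df$logp, "logp", required = TRUE),
    tpsa = parse_numeric_column(df$tpsa, "tpsa", required = TRUE),
    mv = parse_numeric_column(df$mv, "mv", required = TRUE),
    stringsAsFactors = FALSE
  )
  dup <- unique(out$compound_id[duplicated(out$compound_id)])
  if (length(dup)) {
    stop("duplicate compound_id: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad_tpsa <- which(out$tpsa < 0)
  if (length(bad_tpsa)) {
    stop("negative tpsa at row(s) ", paste(bad_tpsa, collapse = ", "),
         call. = FALSE)
  }
  bad_mv <- which(out$mv <= 0)
  if (length(bad_mv)) {
    stop("non-positive mv at row(s) ", paste(bad_mv, collapse = ", "),
         call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' @rdname read_descriptor_table
#' @param descriptors Descriptor data frame to write.
#' @param path Output path.
#' @export
write_descriptor_table <- function(descriptors, path, sep = ",") {
  utils::write.table(descriptors[, c("compound_id", "logp", "tpsa", "mv")],
                     path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Bundle permeability records and descriptors
#'
#' @param records Permeability records ([read_permeability_table()]).
#' @param descriptors Descriptor table ([read_descriptor_table()]).
#' @return A list of class `"huskin_dataset"` with elements `records` and
#'   `descriptors`; records whose compound lacks a descriptor entry are
#'   flagged with a message and counted in `n_without_descriptors`.
#' @export
huskin_dataset <- function(records, descriptors) {
  stopifnot(is.data.frame(records), is.data.frame(descriptors))
  orphan <- !(records$compound_id %in% descriptors$compound_id)
  if (any(orphan)) {
    message(sprintf("%d record(s) have no descriptor entry (%s)",
                    sum(orphan),
                    paste(utils::head(unique(records$compound_id[orphan]), 5),
                          collapse = ", ")))
  }
  structure(list(records = records, descriptors = descriptors,
                 n_without_descriptors = as.integer(sum(orphan))),
            class = "huskin_dataset")
}

#' @export
print.huskin_dataset <- function(x, ...) {
  cat(sprintf(
    "HuskinDB-style dataset: %d Kp record(s), %d compound(s) with descriptors\n",
    nrow(x$records), nrow(x$descriptors)))
  if (x$n_without_descriptors > 0) {
    cat(sprintf("  %d record(s) without descriptors\n",
                x$n_without_descriptors))
  }
  invisible(x)
}

#' Drop records with unspecified experimental conditions
#'
#' Stratification needs all four experimental covariates; records missing
#' any of skin source, skin layer, donor concentration or donor
#' temperature are excluded before scenario assignment (in the source
#' study this removed 71 of 253 compounds). The report breaks exclusions
#' down by which field was missing; a record missing several fields is
#' counted under each.
#'
#' @param records Data frame of permeability records.
#' @return A list with `kept` (records complete in all four fields, input
#'   order preserved) and `report` (data frame with columns `reason`,
#'   `n_records`, `n_compounds` plus attributes `n_excluded` and
#'   `n_excluded_compounds`).
#' @examples
#' rec <- data.frame(compound_id = c("a", "b"), log_kp = c(-5, -6),
#'                   skin_source = c("breast", NA), skin_layer = "epidermis",
#'                   donor_concentration = "diluted",
#'                   donor_temperature_c = c(25, 25))
#' filter_complete(rec)$report
#' @export
filter_complete <- function(records) {
  fields <- c("skin_source", "skin_layer", "donor_concentration",
              "donor_temperature_c")
  if (nrow(records) == 0) {
    report <- data.frame(reason = fields, n_records = 0L, n_compounds = 0L,
                         stringsAsFactors = FALSE)
    attr(report, "n_excluded") <- 0L
    attr(report, "n_excluded_compounds") <- 0L
    return(list(kept = records, report = report))
  }
  miss <- vapply(fields, function(f) is.na(records[[f]]),
                 logical(nrow(records)))
  miss <- matrix(miss, nrow = nrow(records),
                 dimnames = list(NULL, fields))
  excluded <- rowSums(miss) > 0
  report <- data.frame(
    reason = fields,
    n_records = vapply(fields, function(f) sum(miss[, f]), 1L),
    n_compounds = vapply(fields, function(f) {
      length(unique(records$compound_id[miss[, f]]))
    }, 1L),
    stringsAsFactors = FALSE
  )
  rownames(report) <- NULL
  attr(report, "n_excluded") <- as.integer(sum(excluded))
  attr(report, "n_excluded_compounds") <-
    length(unique(records$compound_id[excluded]))
  kept <- records[!excluded, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, report = report)
}

#' Write an exclusion report
#'
#' @param report The `report` element of [filter_complete()]'s result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_exclusion_report <- function(report, path) {
  utils::write.table(report, path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  message(sprintf("excluded %d record(s) across %d compound(s)",
                  attr(report, "n_excluded"),
                  attr(report, "n_excluded_compounds")))
  invisible(path)
}
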