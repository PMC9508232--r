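#' Controlled vocabularies for the experimental stratification variables
#'
#' Four experimental covariates define the stratification grid used before
#' any model is fitted: anatomical skin source, the skin layer mounted in
#' the diffusion cell, the donor-solution concentration class, and the
#' donor-solution temperature bin. Level orders are fixed so that every
#' derived table is reproducible byte-for-byte.
#'
#' @return A character vector of levels, in canonical order.
#' @examples
#' skin_sources()
#' temperature_bins()
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
skin_sources <- function() c("breast", "abdomen", "thigh")

#' @rdname vocabularies
#' @export
skin_layers <- function() {
  c("epidermis", "dermis", "epidermis+dermis", "stratum_corneum")
}

#' @rdname vocabularies
#' @export
donor_concentrations <- function() c("concentrated", "diluted")

#' @rdname vocabularies
#' @export
temperature_bins <- function() c("20-25", "26-30", "31-35", "36-40")

# --- normalizers --------------------------------------------------------

# Each maps raw free-text values onto the controlled vocabulary;
# anything unrecognized becomes NA (counted by callers, never an error).

normalize_skin_source <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[is_blank(x) | x == "na"] <- NA_character_
  out <- ifelse(x %in% skin_sources(), x, NA_character_)
  out
}

normalize_skin_layer <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[is_blank(x) | x == "na"] <- NA_character_
  x <- gsub("\\s*\\+\\s*", "+", x)
  x[!is.na(x) & x %in% c("stratum corneum", "sc")] <- "stratum_corneum"
  ifelse(x %in% skin_layers(), x, NA_character_)
}

#' Normalize donor-concentration wording
#'
#' Permeation studies describe a saturated donor phase as "neat" or
#' "saturated" interchangeably; all three spellings map to
#' `"concentrated"`, and `"dilute"`/`"diluted"` map to `"diluted"`.
#' Anything else (including blanks) becomes `NA`.
#'
#' @param x Character vector of raw donor-concentration values.
#' @return Character vector over `donor_concentrations()` or `NA`.
#' @examples
#' normalize_donor_concentration(c("neat", "Saturated", "dilute", "foam"))
#' @export
normalize_donor_concentration <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[is_blank(x) | x == "na"] <- NA_character_
  out <- rep(NA_character_, length(x))
  out[!is.na(x) & x %in% c("neat", "saturated", "concentrated")] <- "concentrated"
  out[!is.na(x) & x %in% c("diluted", "dilute")] <- "diluted"
  out
}

#' Bin a donor-solution temperature
#'
#' Maps a temperature in degrees Celsius onto the four stratification bins.
#' The printed bin labels are integer ranges (20-25, 26-30, 31-35, 36-40);
#' to make binning total over real-valued temperatures the bins are
#' half-open on the real line: \eqn{[20, 26) \to} "20-25",
#' \eqn{[26, 31) \to} "26-30", \eqn{[31, 36) \to} "31-35",
#' \eqn{[36, 41) \to} "36-40". Temperatures outside \eqn{[20, 41)} (and
#' `NA`) are unassignable and return `NA`.
#'
#' @param t Numeric vector of temperatures, degrees Celsius.
#' @return Character vector over `temperature_bins()` or `NA`.
#' @examples
#' bin_temperature(c(25, 25.5, 26, 37, 19.9, 41.5))
#' @export
bin_temperature <- function(t) {
  t <- as.numeric(t)
  bins <- temperature_bins()
  lo <- c(20, 26, 31, 36)
  hi <- c(26, 31, 36, 41)
  out <- rep(NA_character_, length(t))
  for (i in seq_along(bins)) {
    sel <- !is.na(t) & t >= lo[i] & t < hi[i]
    out[sel] <- bins[i]
  }
  out
}

# numeric bounds of a bin label, used by the synthetic generator
bin_bounds <- function(bin) {
  lo <- c("20-25" = 20, "26-30" = 26, "31-35" = 31, "36-40" = 36)
  c(lo[[bin]], lo[[bin]] + if (bin == "20-25") 6 else 5)
}

#' Scenario keys
#'
#' A scenario is one cell of the skin-source x skin-layer x
#' donor-concentration x temperature-bin grid. Keys are serialized as the
#' four-token string `"source/layer/concentration/bin"` (for example
#' `"abdomen/epidermis/diluted/20-25"`) in all reports and interfaces.
#'
#' @param skin_source,skin_layer,donor_concentration,temperature_bin
#'   Vectors of levels from the corresponding vocabulary.
#' @return `scenario_key()`: a character vector of keys.
#' @examples
#' scenario_key("abdomen", "epidermis", "diluted", "20-25")
#' parse_scenario("abdomen/epidermis/diluted/20-25")
#' @export
scenario_key <- function(skin_source, skin_layer, donor_concentration,
                         temperature_bin) {
  check_level <- function(x, levels, what) {
    bad <- !is.na(x) & !(x %in% levels)
    if (any(bad)) {
      stop(sprintf("invalid %s: %s", what,
                   paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
    }
  }
  check_level(skin_source, skin_sources(), "skin_source")
  check_level(skin_layer, skin_layers(), "skin_layer")
  check_level(donor_concentration, donor_concentrations(), "donor_concentration")
  check_level(temperature_bin, temperature_bins(), "temperature_bin")
  out <- paste(skin_source, skin_layer, donor_concentration, temperature_bin,
               sep = "/")
  out[is.na(skin_source) | is.na(skin_layer) | is.na(donor_concentration) |
        is.na(temperature_bin)] <- NA_character_
  out
}

#' @rdname scenario_key
#' @param key Character vector of serialized scenario keys.
#' @return `parse_scenario()`: a data frame with one row per key and the
#'   four level columns.
#' @export
parse_scenario <- function(key) {
  parts <- strsplit(key, "/", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 4L
  if (any(bad)) {
    stop("malformed scenario key: ", paste(key[bad], collapse = ", "),
         call. = FALSE)
  }
  m <- do.call(rbind, parts)
  out <- data.frame(skin_source = m[, 1], skin_layer = m[, 2],
                    donor_concentration = m[, 3], temperature_bin = m[, 4],
                    stringsAsFactors = FALSE)
  # validate
  scenario_key(out$skin_source, out$skin_layer, out$donor_concentration,
               out$temperature_bin)
  out
}

#' Enumerate the full experimental scenario grid
#'
#' Returns every combination of the four stratification variables exactly
#' once: 3 skin sources x 4 skin layers x 2 donor concentration classes x
#' 4 temperature bins = 96 scenarios. The order is lexicographic over the
#' declared level orders with temperature varying fastest, then
#' concentration, then layer, then source — so `"breast/epidermis/..."`
#' rows come first and `"thigh/stratum_corneum/..."` last.
#'
#' @return `enumerate_scenarios()`: character vector of 96 scenario keys.
#' @examples
#' length(enumerate_scenarios())
#' head(scenario_grid())
#' @export
enumerate_scenarios <- function() {
  g <- scenario_grid()
  scenario_key(g$skin_source, g$skin_layer, g$donor_concentration,
               g$temperature_bin)
}

#' @rdname enumerate_scenarios
#' @return `scenario_grid()`: the same grid as a 96-row data frame.
#' @export
scenario_grid <- function() {
  g <- expand.grid(temperature_bin = temperature_bins(),
                   donor_concentration = donor_concentrations(),
                   skin_layer = skin_layers(),
                   skin_source = skin_sources(),
                   stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  g[, c("skin_source", "skin_layer", "donor_concentration",
        "temperature_bin")]
}

#' Assign permeability records to experimental scenarios
#'
#' Partitions complete permeability records (see [filter_complete()]) into
#' scenario groups, attaching each compound's descriptors. Records whose
#' compound lacks a descriptor entry are dropped with a warning count;
#' complete records whose temperature falls outside all bins are counted
#' as unassignable. Within each group the input row order is preserved,
#' and repeated measurements of the same compound are kept as separate
#' rows.
#'
#' @param records Data frame of permeability records that passed
#'   [filter_complete()].
#' @param descriptors Descriptor table from [read_descriptor_table()].
#' @return An object of class `"scenario_assignment"`: a list with
#'   `groups` (named list of data frames keyed by scenario, ordered as
#'   [enumerate_scenarios()], each with descriptor columns `logp`, `tpsa`,
#'   `mv` merged in), `n_assigned`, `n_unassignable` and
#'   `n_missing_descriptors`.
#' @export
assign_scenarios <- function(records, descriptors) {
  stopifnot(is.data.frame(records), is.data.frame(descriptors))
  if (nrow(records) == 0) {
    out <- list(groups = list(), n_assigned = 0L, n_unassignable = 0L,
                n_missing_descriptors = 0L)
    class(out) <- "scenario_assignment"
    return(out)
  }
  has_desc <- records$compound_id %in% descriptors$compound_id
  n_missing_desc <- sum(!has_desc)
  if (n_missing_desc > 0) {
    warning(sprintf("%d record(s) dropped: no descriptor entry for %s",
                    n_missing_desc,
                    paste(unique(records$compound_id[!has_desc]),
                          collapse = ", ")), call. = FALSE)
  }
  rec <- records[has_desc, , drop = FALSE]
  bin <- bin_temperature(rec$donor_temperature_c)
  key <- scenario_key(rec$skin_source, rec$skin_layer,
                      rec$donor_concentration, bin)
  n_unassignable <- sum(is.na(key))
  rec <- rec[!is.na(key), , drop = FALSE]
  key <- key[!is.na(key)]

  idx <- match(rec$compound_id, descriptors$compound_id)
  rec$logp <- descriptors$logp[idx]
  rec$tpsa <- descriptors$tpsa[idx]
  rec$mv <- descriptors$mv[idx]

  order_keys <- enumerate_scenarios()
  groups <- split(rec, factor(key, levels = order_keys))
  groups <- groups[vapply(groups, nrow, 1L) > 0]
  groups <- lapply(groups, function(g) {
    rownames(g) <- NULL
    g
  })
  out <- list(groups = groups,
              n_assigned = nrow(rec),
              n_unassignable = as.integer(n_unassignable),
              n_missing_descriptors = as.integer(n_missing_desc))
  class(out) <- "scenario_assignment"
  out
}

#' @export
print.scenario_assignment <- function(x, ...) {
  cat(sprintf(
    "Scenario assignment: %d record(s) in %d non-empty scenario(s)\n",
    x$n_assigned, length(x$groups)))
  cat(sprintf("  unassignable temperature: %d; missing descriptors: %d\n",
              x$n_unassignable, x$n_missing_descriptors))
  if (length(x$groups)) {
    sizes <- vapply(x$groups, nrow, 1L)
    cat(sprintf("  group sizes: %s\n",
                paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", ")))
  }
  invisible(x)
}
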