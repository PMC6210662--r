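# Reading, validating and writing GHS hazard tables.

#' Construct a validated GHS record table
#'
#' @param df Data frame with columns \code{cas}, \code{name} and the ten
#'   endpoint columns of \code{\link{ghs_variables}} holding canonical
#'   category labels.
#' @param strict Logical; if \code{TRUE}, categories undefined for an endpoint
#'   (e.g. Category 3 for skin corrosion) raise an error instead of a warning.
#' @return The data frame with class \code{ghs_records}.
#' @export
as_ghs_records <- function(df, strict = FALSE) {
  need <- c("cas", "name", ghs_variables())
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(df)[, need]
  df$cas <- as.character(df$cas)
  df$name <- as.character(df$name)
  for (v in ghs_variables()) {
    df[[v]] <- as.character(df[[v]])
    bad <- !(df[[v]] %in% ghs_categories())
    if (any(bad))
      stop("column ", v, ": invalid category label(s): ",
           paste(unique(df[[v]][bad]), collapse = ", "), call. = FALSE)
    undef <- !(df[[v]] %in% ghs_allowed_categories(v))
    if (any(undef)) {
      msg <- paste0("column ", v, ": category not defined for this endpoint: ",
                    paste(unique(df[[v]][undef]), collapse = ", "))
      if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
    }
  }
  class(df) <- c("ghs_records", "data.frame")
  df
}

#' Read a GHS hazard classification table from CSV
#'
#' Reads a UTF-8 CSV with header columns \code{cas}, \code{name} and either
#' the twelve raw endpoint columns (inhalation split as
#' \code{acute_inhalation_gas} / \code{acute_inhalation_vapor} /
#' \code{acute_inhalation_dust_mist}) or the ten aggregated endpoint columns.
#' Raw category strings are normalized (see \code{\link{normalize_category}}),
#' the three inhalation routes are merged into their most conservative value,
#' rows without a CAS number are dropped and counted, and duplicate CAS rows
#' are deduplicated keeping the first occurrence.
#'
#' @param path Path to the CSV file.
#' @param strict Logical; passed to \code{\link{normalize_category}} and
#'   \code{\link{as_ghs_records}}.
#' @param aliases Optional extra category aliases.
#' @param scheme Quantification scheme defining the conservativeness order
#'   used for the inhalation merge.
#' @return A \code{ghs_records} data frame with attribute \code{io_log}, a
#'   list with counts \code{n_read}, \code{n_dropped_no_cas},
#'   \code{n_deduplicated} and \code{n_kept}.
#' @export
read_ghs_table <- function(path, strict = FALSE, aliases = NULL,
                           scheme = quantification_scheme()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  if (nrow(raw) == 0) stop("empty input table: ", path, call. = FALSE)
  names(raw) <- tolower(trimws(names(raw)))
  has_split <- all(ghs_raw_variables() %in% names(raw))
  has_merged <- all(ghs_variables() %in% names(raw))
  endpoint_cols <- if (has_split) ghs_raw_variables() else ghs_variables()
  miss <- setdiff(c("cas", "name", endpoint_cols), names(raw))
  if (!has_split && !has_merged)
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)

  n_read <- nrow(raw)
  no_cas <- is.na(raw$cas) | trimws(raw$cas) == ""
  raw <- raw[!no_cas, , drop = FALSE]
  raw$cas <- trimws(raw$cas)
  dup <- duplicated(raw$cas)
  raw <- raw[!dup, , drop = FALSE]

  for (v in endpoint_cols) {
    labels <- withCallingHandlers(
      normalize_category(raw[[v]], strict = strict, aliases = aliases),
      warning = function(w) {
        warning("column ", v, ": ", conditionMessage(w), call. = FALSE)
        invokeRestart("muffleWarning")
      })
    raw[[v]] <- labels
  }
  if (has_split) {
    raw$acute_inhalation <- aggregate_inhalation(
      raw$acute_inhalation_gas, raw$acute_inhalation_vapor,
      raw$acute_inhalation_dust_mist, scheme = scheme)
  }
  rec <- as_ghs_records(raw, strict = strict)
  rownames(rec) <- NULL
  attr(rec, "io_log") <- list(n_read = n_read,
                              n_dropped_no_cas = sum(no_cas),
                              n_deduplicated = sum(dup),
                              n_kept = nrow(rec))
  rec
}

#' Write a GHS record table to CSV
#'
#' Writes the aggregated ten-endpoint dialect (readable back by
#' \code{\link{read_ghs_table}}; the read-write-read round trip is exact).
#'
#' @param records A \code{ghs_records} data frame.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_ghs_table <- function(records, path) {
  stopifnot(inherits(records, "ghs_records"))
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Export GHS records as JSON
#'
#' @param records A \code{ghs_records} data frame.
#' @param path Optional output path; if \code{NULL} the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to \code{path}).
#' @export
ghs_records_json <- function(records, path = NULL) {
  stopifnot(inherits(records, "ghs_records"))
  js <- jsonlite::toJSON(as.data.frame(records), dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @export
print.ghs_records <- function(x, ...) {
  cat("GHS hazard records: ", nrow(x), " chemicals, ",
      length(ghs_variables()), " endpoints\n", sep = "")
  log <- attr(x, "io_log")
  if (!is.null(log))
    cat("  read ", log$n_read, ", dropped (no CAS) ", log$n_dropped_no_cas,
        ", deduplicated ", log$n_deduplicated, "\n", sep = "")
  print(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("  ... and ", nrow(x) - 5, " more rows\n", sep = "")
  invisible(x)
}
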