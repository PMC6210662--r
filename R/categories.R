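# GHS hazard categories, endpoint variables and category quantification.

#' GHS hazard category labels
#'
#' The eight ordered classification outcomes a GHS health-hazard endpoint can
#' take: Category 1 (most hazardous) through Category 5, Not Classified
#' (evidence of no hazard at the endpoint), Classification Not Possible
#' (insufficient data -- distinct from evidence of no hazard) and Not
#' Applicable (outside the GHS definition for the endpoint).
#'
#' @return Character vector of the eight canonical category labels.
#' @export
ghs_categories <- function() {
  c("CAT1", "CAT2", "CAT3", "CAT4", "CAT5",
    "NOT_CLASSIFIED", "CLASSIFICATION_NOT_POSSIBLE", "NOT_APPLICABLE")
}

#' GHS health-hazard endpoint variables
#'
#' The ten aggregated health-hazard endpoints used for scoring: three acute
#' toxicity routes (oral, dermal, inhalation -- the latter already merged over
#' gas/vapor/dust-mist), skin corrosion/irritation, serious eye damage/eye
#' irritation, germ cell mutagenicity, carcinogenicity, reproductive toxicity,
#' and specific target organ toxicity after single and repeated exposure.
#'
#' @return Character vector of the ten endpoint column names, in canonical
#'   order.
#' @export
ghs_variables <- function() {
  c("acute_oral", "acute_dermal", "acute_inhalation",
    "skin_corrosion", "eye_damage",
    "mutagenicity", "carcinogenicity", "reproductive",
    "stot_single", "stot_repeated")
}

# Raw (pre-aggregation) column set: inhalation split into three routes.
ghs_raw_variables <- function() {
  c("acute_oral", "acute_dermal",
    "acute_inhalation_gas", "acute_inhalation_vapor", "acute_inhalation_dust_mist",
    "skin_corrosion", "eye_damage",
    "mutagenicity", "carcinogenicity", "reproductive",
    "stot_single", "stot_repeated")
}

# Highest numbered category defined for each endpoint: acute toxicity has
# Categories 1-5; skin, eye, STOT-repeated and the CMR endpoints stop at
# Category 2; STOT-single at Category 3.
ghs_max_category <- function() {
  c(acute_oral = 5L, acute_dermal = 5L, acute_inhalation = 5L,
    skin_corrosion = 2L, eye_damage = 2L,
    mutagenicity = 2L, carcinogenicity = 2L, reproductive = 2L,
    stot_single = 3L, stot_repeated = 2L)
}

# Categories defined for one endpoint (numbered ones up to the endpoint's
# maximum, plus the three non-numbered outcomes).
ghs_allowed_categories <- function(variable) {
  max_cat <- ghs_max_category()[[sub("_(gas|vapor|dust_mist)$", "", variable)]]
  c(paste0("CAT", seq_len(max_cat)),
    "NOT_CLASSIFIED", "CLASSIFICATION_NOT_POSSIBLE", "NOT_APPLICABLE")
}

#' Quantification scheme for GHS categories
#'
#' Maps each hazard category to a numeric score (points). The default assigns
#' Category n the score 100/n (Category 1 = 100, the most hazardous), Not
#' Classified 10 points (below Category 5), Classification Not Possible 30
#' points (near Category 3, because absence of information is not absence of
#' hazard) and Not Applicable 1 point.
#'
#' @param overrides Named numeric vector of score overrides, names among
#'   \code{ghs_categories()}.
#' @return Named numeric vector of class \code{quantification_scheme} mapping
#'   every category label to a strictly positive score, with Category 1
#'   maximal.
#' @examples
#' sc <- quantification_scheme()
#' sc[["CAT1"]] # 100
#' @export
quantification_scheme <- function(overrides = NULL) {
  scores <- c(CAT1 = 100, CAT2 = 50, CAT3 = 100 / 3, CAT4 = 25, CAT5 = 20,
              NOT_CLASSIFIED = 10, CLASSIFICATION_NOT_POSSIBLE = 30,
              NOT_APPLICABLE = 1)
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || !all(names(overrides) %in% names(scores)))
      stop("overrides must be named with GHS category labels", call. = FALSE)
    scores[names(overrides)] <- overrides
  }
  if (any(scores <= 0))
    stop("all category scores must be strictly positive", call. = FALSE)
  if (scores[["CAT1"]] < max(scores))
    stop("CAT1 must carry the maximum score", call. = FALSE)
  structure(scores, class = "quantification_scheme")
}

# Category alias table. Keys are lower-cased, trimmed input strings; GHS
# sub-categories 1A/1B (CMR endpoints) collapse to Category 1.
category_alias_table <- function() {
  al <- c(
    "1" = "CAT1", "1a" = "CAT1", "1b" = "CAT1",
    "2" = "CAT2", "3" = "CAT3", "4" = "CAT4", "5" = "CAT5",
    "category 1" = "CAT1", "category 1a" = "CAT1", "category 1b" = "CAT1",
    "category 2" = "CAT2", "category 3" = "CAT3",
    "category 4" = "CAT4", "category 5" = "CAT5",
    "cat1" = "CAT1", "cat2" = "CAT2", "cat3" = "CAT3",
    "cat4" = "CAT4", "cat5" = "CAT5",
    "nc" = "NOT_CLASSIFIED", "not classified" = "NOT_CLASSIFIED",
    "not_classified" = "NOT_CLASSIFIED",
    "cnp" = "CLASSIFICATION_NOT_POSSIBLE",
    "classification not possible" = "CLASSIFICATION_NOT_POSSIBLE",
    "classification_not_possible" = "CLASSIFICATION_NOT_POSSIBLE",
    "na" = "NOT_APPLICABLE", "n/a" = "NOT_APPLICABLE",
    "not applicable" = "NOT_APPLICABLE", "not_applicable" = "NOT_APPLICABLE")
  al
}

#' Normalize raw category strings
#'
#' Trims and lower-cases raw strings, resolves aliases ("1A", "Not
#' classified", "NC", ...) to canonical labels, and treats empty cells as
#' Classification Not Possible (missing information) with a warning.
#'
#' @param x Character vector of raw category strings.
#' @param strict Logical; if \code{TRUE}, unknown strings raise an error, if
#'   \code{FALSE} they become Classification Not Possible with a warning.
#' @param aliases Named character vector extending the built-in alias table.
#' @return Character vector of canonical category labels.
#' @export
normalize_category <- function(x, strict = FALSE, aliases = NULL) {
  tab <- category_alias_table()
  if (!is.null(aliases)) {
    names(aliases) <- tolower(trimws(names(aliases)))
    tab[names(aliases)] <- aliases
  }
  key <- tolower(trimws(as.character(x)))
  out <- ifelse(toupper(key) %in% ghs_categories(), toupper(key),
                unname(tab[key]))
  missing_cell <- is.na(x) | key == ""
  if (any(missing_cell)) {
    out[missing_cell] <- "CLASSIFICATION_NOT_POSSIBLE"
    warning(sum(missing_cell),
            " empty cell(s) treated as CLASSIFICATION_NOT_POSSIBLE",
            call. = FALSE)
  }
  unknown <- is.na(out)
  if (any(unknown)) {
    msg <- paste0("unparseable category string(s): ",
                  paste(unique(x[unknown]), collapse = ", "))
    if (strict) stop(msg, call. = FALSE)
    warning(msg, "; treated as CLASSIFICATION_NOT_POSSIBLE", call. = FALSE)
    out[unknown] <- "CLASSIFICATION_NOT_POSSIBLE"
  }
  out
}

#' Conservativeness order of categories
#'
#' Orders category labels from most to least conservative by descending score
#' under a quantification scheme (default: Category 1 > 2 > 3 >
#' Classification Not Possible > Category 4 > 5 > Not Classified > Not
#' Applicable).
#'
#' @param scheme A \code{\link{quantification_scheme}}.
#' @return Character vector of labels, most conservative first.
#' @export
conservativeness_order <- function(scheme = quantification_scheme()) {
  names(sort(unclass(scheme), decreasing = TRUE))
}

#' Merge the three inhalation routes into one endpoint
#'
#' GHS classifies acute inhalation toxicity separately for gases, vapors and
#' dusts/mists; for scoring they are merged into the single most conservative
#' value, where conservativeness follows the quantification scheme's score
#' order. The merge is commutative in its arguments.
#'
#' @param gas,vapor,dust_mist Character vectors of canonical category labels
#'   (recycled to common length).
#' @param scheme \code{\link{quantification_scheme}} defining the order.
#' @return Character vector of merged category labels.
#' @examples
#' aggregate_inhalation("CAT2", "CAT4", "NOT_CLASSIFIED") # "CAT2"
#' @export
aggregate_inhalation <- function(gas, vapor, dust_mist,
                                 scheme = quantification_scheme()) {
  m <- cbind(as.character(gas), as.character(vapor), as.character(dust_mist))
  bad <- !(m %in% ghs_categories())
  if (any(bad))
    stop("invalid category label(s): ", paste(unique(m[bad]), collapse = ", "),
         call. = FALSE)
  sc <- matrix(unclass(scheme)[m], nrow = nrow(m))
  m[cbind(seq_len(nrow(m)), max.col(sc, ties.method = "first"))]
}
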