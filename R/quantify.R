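# Quantification of GHS records into per-endpoint score vectors.

#' Quantify GHS records into numeric score vectors
#'
#' Maps every endpoint category through a quantification scheme and appends
#' the total over the ten endpoints. The mapping is monotone: replacing any
#' endpoint by a more conservative category never decreases the total.
#'
#' @param records A \code{ghs_records} data frame (see
#'   \code{\link{as_ghs_records}}).
#' @param scheme A \code{\link{quantification_scheme}}.
#' @return Data frame of class \code{ghs_scores} with columns \code{cas},
#'   \code{name}, the ten endpoint scores and \code{total}.
#' @examples
#' rec <- fixture_flutolanil()
#' ghs_quantify(rec)$total # 120
#' @export
ghs_quantify <- function(records, scheme = quantification_scheme()) {
  stopifnot(inherits(records, "ghs_records"))
  sc <- unclass(scheme)
  out <- data.frame(cas = records$cas, name = records$name,
                    stringsAsFactors = FALSE)
  for (v in ghs_variables()) {
    lab <- records[[v]]
    if (any(!(lab %in% names(sc))))
      stop("endpoint ", v, ": category absent from quantification scheme",
           call. = FALSE)
    out[[v]] <- unname(sc[lab])
  }
  out$total <- rowSums(as.matrix(out[, ghs_variables()]))
  class(out) <- c("ghs_scores", "data.frame")
  attr(out, "scheme") <- scheme
  out
}

# Numeric score matrix (chemicals x endpoints) from a ghs_scores table.
score_matrix <- function(scores) {
  stopifnot(inherits(scores, "ghs_scores"))
  m <- as.matrix(as.data.frame(scores)[, ghs_variables()])
  rownames(m) <- scores$cas
  m
}

#' Write quantified scores to CSV
#'
#' @param scores A \code{ghs_scores} data frame.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_score_table <- function(scores, path) {
  stopifnot(inherits(scores, "ghs_scores"))
  utils::write.csv(as.data.frame(scores), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
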