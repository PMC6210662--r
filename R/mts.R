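# Mahalanobis-Taguchi System core: unit-space construction and scaled
# Mahalanobis distances.

#' Selection criteria for the low-hazard reference group
#'
#' The unit space (Mahalanobis space) is built from chemicals with relatively
#' low health hazard: at most \code{max_cat1} Category 1 endpoints, at most
#' \code{max_cat2} Category 2 endpoints, and a total quantified score of at
#' most \code{total_limit} points over the ten endpoints.
#'
#' @param max_cat1,max_cat2 Maximum allowed count of Category 1 / Category 2
#'   endpoint classifications (default 0).
#' @param total_limit Total-score ceiling in points (default 280).
#' @param inclusive Logical; if \code{TRUE} (default) the ceiling is
#'   inclusive (total \eqn{\le} limit), otherwise strict.
#' @return List of class \code{selection_criteria}.
#' @export
selection_criteria <- function(max_cat1 = 0L, max_cat2 = 0L,
                               total_limit = 280, inclusive = TRUE) {
  stopifnot(max_cat1 >= 0, max_cat2 >= 0, total_limit > 0)
  structure(list(max_cat1 = as.integer(max_cat1),
                 max_cat2 = as.integer(max_cat2),
                 total_limit = total_limit, inclusive = inclusive),
            class = "selection_criteria")
}

#' Select the low-hazard normal group
#'
#' Applies \code{\link{selection_criteria}} deterministically to quantified
#' records: chemicals with too many Category 1 or Category 2 classifications
#' or too high a total score are excluded.
#'
#' @param records A \code{ghs_records} data frame.
#' @param scores The matching \code{ghs_scores} table (same CAS set).
#' @param criteria A \code{\link{selection_criteria}} object.
#' @return Character vector of member CAS numbers.
#' @export
select_normal_group <- function(records, scores = ghs_quantify(records),
                                criteria = selection_criteria()) {
  stopifnot(inherits(records, "ghs_records"), inherits(scores, "ghs_scores"))
  if (!setequal(records$cas, scores$cas))
    stop("records and scores must cover the same CAS set", call. = FALSE)
  scores <- scores[match(records$cas, scores$cas), ]
  cats <- as.matrix(as.data.frame(records)[, ghs_variables()])
  n1 <- rowSums(cats == "CAT1")
  n2 <- rowSums(cats == "CAT2")
  ok_total <- if (criteria$inclusive) scores$total <= criteria$total_limit
              else scores$total < criteria$total_limit
  keep <- n1 <= criteria$max_cat1 & n2 <= criteria$max_cat2 & ok_total
  members <- records$cas[keep]
  k <- length(ghs_variables())
  if (length(members) < k + 2)
    stop("only ", length(members), " chemicals satisfy the selection ",
         "criteria; at least ", k + 2, " are required for a stable ",
         "correlation matrix -- relax max_cat1/max_cat2 or total_limit",
         call. = FALSE)
  members
}

#' Fit the unit-space reference statistics
#'
#' Computes per-endpoint means and standard deviations (n-1 divisor), the
#' sample correlation matrix of the member score vectors, and its inverse.
#' Endpoints with zero variance among members are flagged as degenerate and
#' excluded from the correlation matrix and the distance. When the smallest
#' eigenvalue of the correlation matrix falls below \code{tol} times the
#' largest, the Moore-Penrose pseudoinverse replaces the plain inverse.
#'
#' @param member_scores \code{ghs_scores} table restricted to unit-space
#'   members, or any data frame with \code{cas} plus the ten endpoint score
#'   columns.
#' @param tol Relative eigenvalue threshold for declaring near-singularity.
#' @return Object of class \code{reference_space}: list with
#'   \code{variables}, \code{means}, \code{sds}, \code{corr},
#'   \code{corr_inv}, \code{pseudo} (logical), \code{degenerate} (excluded
#'   endpoint names), \code{n_members}, \code{member_cas}.
#' @export
fit_reference <- function(member_scores, tol = 1e-10) {
  m <- if (inherits(member_scores, "ghs_scores")) score_matrix(member_scores)
       else {
         stopifnot(all(c("cas", ghs_variables()) %in% names(member_scores)))
         mm <- as.matrix(member_scores[, ghs_variables()])
         rownames(mm) <- member_scores$cas
         mm
       }
  n <- nrow(m)
  k_all <- ncol(m)
  if (n < k_all + 2)
    stop("need at least ", k_all + 2, " members to fit the reference space, ",
         "got ", n, call. = FALSE)
  means <- colMeans(m)
  sds <- apply(m, 2, stats::sd)
  degenerate <- colnames(m)[sds <= .Machine$double.eps^0.5 * pmax(abs(means), 1)]
  active <- setdiff(colnames(m), degenerate)
  if (length(active) == 0)
    stop("all endpoints are constant across members; no reference space ",
         "can be fitted", call. = FALSE)
  corr <- stats::cor(m[, active, drop = FALSE])
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  pseudo <- min(ev) < tol * max(ev)
  corr_inv <- if (pseudo) MASS::ginv(corr) else solve(corr)
  dimnames(corr_inv) <- dimnames(corr)
  if (length(degenerate) > 0)
    warning("degenerate (zero-variance) endpoint(s) excluded from the ",
            "correlation structure: ", paste(degenerate, collapse = ", "),
            call. = FALSE)
  structure(list(variables = colnames(m), means = means, sds = sds,
                 corr = corr, corr_inv = corr_inv, pseudo = pseudo,
                 eigenvalues = ev, degenerate = degenerate,
                 n_members = n, member_cas = rownames(m)),
            class = "reference_space")
}

#' Scaled Mahalanobis distance of score vectors from the unit space
#'
#' For a score vector \eqn{x}, the scaled Mahalanobis distance is
#' \deqn{MD = z' R^{-1} z / k,} where \eqn{z_i = (x_i - \bar x_i)/s_i} uses
#' the unit-space mean and standard deviation, \eqn{R} is the unit-space
#' correlation matrix and \eqn{k} the number of non-degenerate endpoints.
#' Chemicals near the unit-space centre score near 0; unit-space members
#' average \eqn{(n-1)/n} by construction.
#'
#' @param scores \code{ghs_scores} table (or data frame with \code{cas} and
#'   endpoint score columns) for the chemicals to score.
#' @param ref A \code{\link{fit_reference}} object.
#' @param scale_by_k Logical; divide by the number of endpoints (default
#'   \code{TRUE}, the conventional MTS scaling).
#' @return Numeric vector of distances, named by CAS.
#' @export
mahalanobis_distance <- function(scores, ref, scale_by_k = TRUE) {
  stopifnot(inherits(ref, "reference_space"))
  m <- if (inherits(scores, "ghs_scores")) score_matrix(scores)
       else if (is.matrix(scores)) scores
       else {
         mm <- as.matrix(scores[, ghs_variables()])
         rownames(mm) <- scores$cas
         mm
       }
  active <- setdiff(ref$variables, ref$degenerate)
  miss <- setdiff(active, colnames(m))
  if (length(miss) > 0)
    stop("score table lacks endpoint(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  z <- sweep(sweep(m[, active, drop = FALSE], 2, ref$means[active]),
             2, ref$sds[active], "/")
  md <- rowSums((z %*% ref$corr_inv) * z)
  if (scale_by_k) md <- md / length(active)
  # pseudoinverse roundoff can leave tiny negative values at the centre
  pmax(md, 0)
}

#' Score and rank every chemical by Mahalanobis distance
#'
#' Computes the scaled Mahalanobis distance of each chemical from the
#' unit-space centre and assigns competition ranks (rank 1 = largest
#' distance; ties share the smallest applicable rank and the next rank is
#' skipped). Unit-space members are scored like every other chemical.
#'
#' @inheritParams mahalanobis_distance
#' @return Data frame of class \code{md_ranking} with columns \code{cas},
#'   \code{name} (when available), \code{md} and \code{rank}, in input order.
#' @export
mahalanobis_score <- function(scores, ref, scale_by_k = TRUE) {
  md <- mahalanobis_distance(scores, ref, scale_by_k = scale_by_k)
  out <- data.frame(cas = names(md), md = unname(md),
                    stringsAsFactors = FALSE)
  if (!is.null(scores$name)) out$name <- scores$name
  out$rank <- as.integer(rank(-out$md, ties.method = "min"))
  out <- out[, intersect(c("cas", "name", "md", "rank"), names(out))]
  class(out) <- c("md_ranking", "data.frame")
  out
}

#' Top of a Mahalanobis ranking
#'
#' @param ranking An \code{md_ranking} data frame.
#' @param n Number of chemicals to report.
#' @return The \code{n} rows with the largest distances, ordered by rank.
#' @export
top_hazards <- function(ranking, n = 10) {
  stopifnot(inherits(ranking, "md_ranking"))
  ord <- order(ranking$rank, ranking$cas)
  utils::head(ranking[ord, ], n)
}

#' Serialize reference-space statistics to JSON
#'
#' @param ref A \code{reference_space} object.
#' @param path Optional output path.
#' @return JSON string (invisibly when written).
#' @export
reference_json <- function(ref, path = NULL) {
  stopifnot(inherits(ref, "reference_space"))
  payload <- list(variables = ref$variables,
                  means = as.list(ref$means), sds = as.list(ref$sds),
                  corr = ref$corr, corr_inv = ref$corr_inv,
                  pseudoinverse = ref$pseudo, degenerate = ref$degenerate,
                  n_members = ref$n_members, member_cas = ref$member_cas)
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @export
print.reference_space <- function(x, ...) {
  cat("Unit space: ", x$n_members, " member chemicals, ",
      length(x$variables) - length(x$degenerate), " active endpoints",
      if (x$pseudo) " (pseudoinverse)", "\n", sep = "")
  if (length(x$degenerate) > 0)
    cat("  degenerate: ", paste(x$degenerate, collapse = ", "), "\n", sep = "")
  stats <- rbind(mean = x$means, sd = x$sds)
  print(round(stats, 3))
  invisible(x)
}
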