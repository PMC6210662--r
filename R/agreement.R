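# Agreement with external chemical ranking and scoring (CRS) methods and
# validation against regulatory chemical lists.

#' Pearson correlation between two hazard score sets
#'
#' Sample Pearson correlation with a two-sided t test on n - 2 degrees of
#' freedom, via \code{stats::cor.test}.
#'
#' @param x,y Numeric score vectors of equal length (\eqn{\ge 3}),
#'   non-constant.
#' @return List with \code{r}, \code{p} and \code{n}.
#' @export
score_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 paired scores", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant scores", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Cross-classification table of two grade assignments
#'
#' @param a,b \code{grade_assignment} objects over the same chemical set and
#'   the same number of classes.
#' @return A \code{k x k} contingency matrix: rows = grades under \code{a},
#'   columns = grades under \code{b}.
#' @export
grade_contingency <- function(a, b) {
  stopifnot(inherits(a, "grade_assignment"), inherits(b, "grade_assignment"))
  if (a$k != b$k)
    stop("grade assignments use different numbers of classes", call. = FALSE)
  if (!setequal(a$grades$cas, b$grades$cas)) {
    d <- c(setdiff(a$grades$cas, b$grades$cas),
           setdiff(b$grades$cas, a$grades$cas))
    stop("chemical sets differ between assignments: ",
         paste(utils::head(d, 10), collapse = ", "),
         if (length(d) > 10) " ...", call. = FALSE)
  }
  ga <- a$grades$grade[order(a$grades$cas)]
  gb <- b$grades$grade[order(b$grades$cas)]
  lev <- seq_len(a$k)
  tab <- table(factor(ga, levels = lev), factor(gb, levels = lev))
  unclass(as.matrix(tab))
}

#' Weighted Cohen's kappa from a contingency table
#'
#' Chance-corrected agreement using the disagreement-weight formulation
#' \deqn{\kappa_w = 1 - \frac{\sum_{ij} w_{ij} o_{ij}}{\sum_{ij} w_{ij} e_{ij}},}
#' with observed proportions \eqn{o}, expected proportions \eqn{e} (outer
#' product of the marginals), and weights \eqn{w_{ij} = (|i-j|/(k-1))^p}
#' for linear (\eqn{p = 1}) and quadratic (\eqn{p = 2}) weighting, or
#' \eqn{w_{ij} = 1\{i \ne j\}} unweighted.
#'
#' @param table Square numeric matrix of co-classification counts.
#' @param weighting One of \code{"unweighted"}, \code{"linear"},
#'   \code{"quadratic"}.
#' @return Kappa as a single number in \eqn{[-\infty, 1]}.
#' @examples
#' weighted_kappa(matrix(c(20, 10, 5, 15), 2), "unweighted") # 0.4
#' @export
weighted_kappa <- function(table,
                           weighting = c("unweighted", "linear", "quadratic")) {
  weighting <- match.arg(weighting)
  stopifnot(is.matrix(table), nrow(table) == ncol(table))
  n <- sum(table)
  if (n <= 0) stop("empty contingency table", call. = FALSE)
  k <- nrow(table)
  o <- table / n
  e <- outer(rowSums(o), colSums(o))
  idx <- abs(outer(seq_len(k), seq_len(k), "-"))
  w <- switch(weighting,
              unweighted = (idx != 0) * 1,
              linear = idx / (k - 1),
              quadratic = (idx / (k - 1))^2)
  expected_disagreement <- sum(w * e)
  if (expected_disagreement == 0) {
    warning("no expected disagreement (all mass in one cell); kappa ",
            "defined as 1", call. = FALSE)
    return(1)
  }
  1 - sum(w * o) / expected_disagreement
}

#' Agreement report between two score sets
#'
#' Convenience wrapper: Pearson correlation of the raw scores plus
#' unweighted, linear- and quadratic-weighted kappa of their grade
#' assignments under one classification method.
#'
#' @param x,y Named numeric score vectors (names = CAS) over the same
#'   chemical set.
#' @param method Class-interval method passed to
#'   \code{\link{classify_scores}}.
#' @param k Number of classes.
#' @return List of class \code{agreement_report}: \code{pearson_r},
#'   \code{pearson_p}, \code{kappa_unweighted}, \code{kappa_linear},
#'   \code{kappa_quadratic}, \code{method}, \code{k}, \code{n}.
#' @export
agreement_report <- function(x, y, method = "jenks", k = 4) {
  stopifnot(!is.null(names(x)), !is.null(names(y)))
  common <- intersect(names(x), names(y))
  if (!setequal(names(x), names(y)))
    warning(length(x) + length(y) - 2 * length(common),
            " unmatched chemical(s) dropped from the comparison",
            call. = FALSE)
  x <- x[common]; y <- y[common]
  ct <- score_correlation(unname(x), unname(y))
  tab <- grade_contingency(classify_scores(x, method, k),
                           classify_scores(y, method, k))
  structure(list(pearson_r = ct$r, pearson_p = ct$p,
                 kappa_unweighted = weighted_kappa(tab, "unweighted"),
                 kappa_linear = weighted_kappa(tab, "linear"),
                 kappa_quadratic = weighted_kappa(tab, "quadratic"),
                 contingency = tab, method = method, k = k,
                 n = length(common)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Agreement (", x$method, ", k = ", x$k, ", n = ", x$n, ")\n", sep = "")
  cat(sprintf("  Pearson r = %.3f (p = %.3g)\n", x$pearson_r, x$pearson_p))
  cat(sprintf("  kappa: unweighted %.3f, linear %.3f, quadratic %.3f\n",
              x$kappa_unweighted, x$kappa_linear, x$kappa_quadratic))
  invisible(x)
}

#' Validation against a regulatory chemical list
#'
#' True-positive proportion: fraction of regulated chemicals placed in the
#' high-hazard grades. False-positive proportion: fraction of non-regulated
#' chemicals placed there.
#'
#' @param grades A \code{grade_assignment}.
#' @param regulated Character vector of regulated CAS numbers.
#' @param high_grades Grades counted as high-hazard (default 3 and 4).
#' @return List of class \code{validation_report} with \code{tp},
#'   \code{fp} (proportions), \code{tp_count}, \code{fp_count},
#'   \code{n_regulated}, \code{n_unregulated}.
#' @export
regulatory_validation <- function(grades, regulated, high_grades = c(3, 4)) {
  stopifnot(inherits(grades, "grade_assignment"))
  regulated <- unique(as.character(regulated))
  if (length(regulated) == 0)
    stop("regulated chemical list is empty", call. = FALSE)
  g <- grades$grades
  unmatched <- setdiff(regulated, g$cas)
  if (length(unmatched) > 0) {
    warning(length(unmatched), " regulated CAS number(s) not in the graded ",
            "set; dropped", call. = FALSE)
    regulated <- setdiff(regulated, unmatched)
    if (length(regulated) == 0)
      stop("no regulated chemical matches the graded set", call. = FALSE)
  }
  high <- g$cas[g$grade %in% high_grades]
  reg <- g$cas %in% regulated
  n_reg <- sum(reg)
  n_unreg <- sum(!reg)
  tp_count <- length(intersect(high, g$cas[reg]))
  fp_count <- length(intersect(high, g$cas[!reg]))
  structure(list(tp = tp_count / n_reg,
                 fp = if (n_unreg > 0) fp_count / n_unreg else NA_real_,
                 tp_count = tp_count, fp_count = fp_count,
                 n_regulated = n_reg, n_unregulated = n_unreg,
                 high_grades = high_grades),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Regulatory validation (high grades: %s)\n",
              paste(x$high_grades, collapse = ", ")))
  cat(sprintf("  true positive:  %.1f%% (%d/%d)\n", 100 * x$tp, x$tp_count,
              x$n_regulated))
  cat(sprintf("  false positive: %.1f%% (%d/%d)\n", 100 * x$fp, x$fp_count,
              x$n_unregulated))
  invisible(x)
}

#' Per-group score means with 95\% confidence intervals
#'
#' Arithmetic mean and Student-t confidence interval
#' (\eqn{\bar x \pm t_{0.975, n-1} s/\sqrt n}) of a score per group label
#' (e.g. regulatory chemical type). Singleton groups report their mean with
#' an undefined interval. Chemicals whose CAS carries no group label are
#' collected under \code{"other"}.
#'
#' @param scores Named numeric score vector (names = CAS) or data frame
#'   accepted by the grading functions.
#' @param groups Named character vector mapping CAS to group label.
#' @param conf_level Confidence level (default 0.95).
#' @return Data frame with \code{group}, \code{n}, \code{mean},
#'   \code{ci_lower}, \code{ci_upper} (NA for singletons).
#' @export
group_summary <- function(scores, groups, conf_level = 0.95) {
  fr <- as_score_frame(scores)
  lab <- groups[fr$cas]
  lab[is.na(lab)] <- "other"
  out <- do.call(rbind, lapply(split(fr$score, lab), function(v) {
    n <- length(v)
    m <- mean(v)
    if (n > 1) {
      half <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1) *
        stats::sd(v) / sqrt(n)
      c(n = n, mean = m, ci_lower = m - half, ci_upper = m + half)
    } else {
      c(n = n, mean = m, ci_lower = NA_real_, ci_upper = NA_real_)
    }
  }))
  data.frame(group = rownames(out), out, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Read a regulated-chemical list
#'
#' Plain text, one CAS number per line; blank lines and \code{#} comments
#' ignored.
#'
#' @param path Path to the list file.
#' @return Character vector of CAS numbers.
#' @export
read_regulated_list <- function(path) {
  lines <- trimws(readLines(path, encoding = "UTF-8"))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}
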