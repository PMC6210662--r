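# Class-interval methods: partition a hazard score distribution into k
# ordered grades (grade 1 = least hazardous ... grade k = most hazardous).

# Canonical (cas, score) representation. Accepts a named numeric vector, an
# md_ranking (uses md), a ghs_scores table (uses total), or any data frame
# with a cas column and one of score/md/total.
as_score_frame <- function(scores) {
  if (is.numeric(scores)) {
    if (is.null(names(scores)))
      stop("numeric score vectors must be named by CAS", call. = FALSE)
    return(data.frame(cas = names(scores), score = unname(scores),
                      stringsAsFactors = FALSE))
  }
  stopifnot(is.data.frame(scores), "cas" %in% names(scores))
  col <- intersect(c("score", "md", "total"), names(scores))[1]
  if (is.na(col))
    stop("no score column (score/md/total) found", call. = FALSE)
  data.frame(cas = as.character(scores$cas), score = as.numeric(scores[[col]]),
             stringsAsFactors = FALSE)
}

# Grades from strictly ascending breaks: half-open intervals [low, high),
# final class closed; a value exactly on a break goes to the upper class.
grades_from_breaks <- function(x, breaks, k) {
  g <- findInterval(x, breaks) + 1L
  pmin(g, k)
}

new_grade_assignment <- function(method, k, breaks, frame) {
  frame$grade <- grades_from_breaks(frame$score, breaks, k)
  structure(list(method = method, k = as.integer(k),
                 breaks = as.numeric(breaks), grades = frame),
            class = "grade_assignment")
}

degenerate_assignment <- function(method, k, frame) {
  warning("all scores identical; every chemical assigned grade 1",
          call. = FALSE)
  frame$grade <- 1L
  structure(list(method = method, k = as.integer(k), breaks = numeric(0),
                 grades = frame), class = "grade_assignment")
}

#' Equal-interval classification
#'
#' Breaks at \code{min + i (max - min) / k}: classes of equal score width.
#'
#' @param scores Scores as a named numeric vector or data frame with
#'   \code{cas} and a score column.
#' @param k Number of classes (default 4).
#' @return A \code{grade_assignment}: list with \code{method}, \code{k},
#'   ascending \code{breaks} and a \code{grades} data frame (\code{cas},
#'   \code{score}, \code{grade}).
#' @export
classify_equal_interval <- function(scores, k = 4) {
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  fr <- as_score_frame(scores)
  rng <- range(fr$score)
  if (diff(rng) == 0) return(degenerate_assignment("equal_interval", k, fr))
  breaks <- rng[1] + seq_len(k - 1) * diff(rng) / k
  new_grade_assignment("equal_interval", k, breaks, fr)
}

#' Quantile classification
#'
#' Classes of (near-)equal occupancy. Cut candidates are the \code{i/k}
#' empirical quantiles (inverse empirical CDF, type 1); each break is placed
#' at the smallest data value strictly above its quantile, so tied values are
#' never split across classes and the boundary convention (value on a break
#' goes up) is preserved. With four classes this is quartile classification.
#'
#' @inheritParams classify_equal_interval
#' @return A \code{grade_assignment}.
#' @export
classify_quantile <- function(scores, k = 4) {
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  fr <- as_score_frame(scores)
  x <- fr$score
  if (diff(range(x)) == 0) return(degenerate_assignment("quantile", k, fr))
  qs <- stats::quantile(x, probs = seq_len(k - 1) / k, type = 1, names = FALSE)
  breaks <- vapply(qs, function(q) {
    above <- x[x > q]
    if (length(above) == 0) NA_real_ else min(above)
  }, numeric(1))
  breaks <- sort(unique(breaks[!is.na(breaks)]))
  if (length(breaks) < k - 1)
    warning("heavy ties: only ", length(breaks) + 1,
            " distinct quantile classes formed", call. = FALSE)
  new_grade_assignment("quantile", k, breaks, fr)
}

# Exact Fisher-Jenks dynamic program on weighted unique values.
# Returns the k-1 break values (first value of classes 2..k).
jenks_breaks <- function(x, k) {
  xs <- sort(x)
  v <- unique(xs)                 # exact doubles; no string round-trip
  w <- tabulate(match(xs, v), nbins = length(v))
  m <- length(v)
  k_eff <- min(k, m)
  cw <- c(0, cumsum(w))
  cv <- c(0, cumsum(w * v))
  cv2 <- c(0, cumsum(w * v * v))
  # weighted within-block sum of squares over unique-value blocks i..j,
  # vectorized over the block start i (prefix-sum identity)
  ssd_to <- function(i, j) {
    sw <- cw[j + 1] - cw[i]
    sv <- cv[j + 1] - cv[i]
    sv2 <- cv2[j + 1] - cv2[i]
    sv2 - sv * sv / sw
  }
  D <- matrix(Inf, nrow = k_eff, ncol = m)
  B <- matrix(1L, nrow = k_eff, ncol = m) # first index of the last class
  D[1, ] <- ssd_to(1, seq_len(m))
  if (k_eff > 1) {
    for (cls in 2:k_eff) {
      for (j in cls:m) {
        i_cand <- cls:j
        cost <- D[cls - 1, i_cand - 1] + ssd_to(i_cand, j)
        best <- which.min(cost)
        D[cls, j] <- cost[best]
        B[cls, j] <- i_cand[best]
      }
    }
  }
  starts <- integer(k_eff)
  j <- m
  for (cls in k_eff:1) {
    starts[cls] <- B[cls, j]
    j <- starts[cls] - 1
  }
  list(breaks = v[starts[-1]], ssd = D[k_eff, m])
}

#' Fisher-Jenks natural-breaks classification
#'
#' Exact dynamic program minimizing the total within-class sum of squared
#' deviations from class means; breaks fall in the natural gaps of the
#' distribution.
#'
#' @inheritParams classify_equal_interval
#' @return A \code{grade_assignment}; attribute \code{ssd} on the object
#'   carries the optimal within-class sum of squares.
#' @export
classify_jenks <- function(scores, k = 4) {
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  fr <- as_score_frame(scores)
  if (nrow(fr) < k)
    stop("need at least k = ", k, " observations, got ", nrow(fr),
         call. = FALSE)
  if (diff(range(fr$score)) == 0)
    return(degenerate_assignment("jenks", k, fr))
  jb <- jenks_breaks(fr$score, k)
  out <- new_grade_assignment("jenks", k, jb$breaks, fr)
  out$ssd <- jb$ssd
  out
}

#' Geometric-interval classification
#'
#' Multiplicative (log-equal) breaks \code{min * (max/min)^(i/k)}: class
#' widths form a geometric progression, suited to right-skewed score
#' distributions such as Mahalanobis distances. Non-positive minima are
#' handled by shifting scores by \code{1 - min} before the rule and shifting
#' the breaks back.
#'
#' @inheritParams classify_equal_interval
#' @return A \code{grade_assignment}.
#' @export
classify_geometric_interval <- function(scores, k = 4) {
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  fr <- as_score_frame(scores)
  x <- fr$score
  if (diff(range(x)) == 0)
    return(degenerate_assignment("geometric_interval", k, fr))
  shift <- if (min(x) <= 0) 1 - min(x) else 0
  y <- x + shift
  breaks <- min(y) * (max(y) / min(y))^(seq_len(k - 1) / k) - shift
  new_grade_assignment("geometric_interval", k, breaks, fr)
}

#' Classify scores by a named class-interval method
#'
#' @inheritParams classify_equal_interval
#' @param method One of \code{"equal_interval"}, \code{"quantile"},
#'   \code{"jenks"}, \code{"geometric_interval"}.
#' @return A \code{grade_assignment}.
#' @export
classify_scores <- function(scores,
                            method = c("equal_interval", "quantile",
                                       "jenks", "geometric_interval"),
                            k = 4) {
  method <- match.arg(method)
  switch(method,
         equal_interval = classify_equal_interval(scores, k),
         quantile = classify_quantile(scores, k),
         jenks = classify_jenks(scores, k),
         geometric_interval = classify_geometric_interval(scores, k))
}

#' Within-class sum of squared deviations of a grade assignment
#'
#' @param assignment A \code{grade_assignment}.
#' @return Total within-class sum of squares around class means.
#' @export
within_class_ssd <- function(assignment) {
  stopifnot(inherits(assignment, "grade_assignment"))
  g <- assignment$grades
  sum(vapply(split(g$score, g$grade),
             function(v) sum((v - mean(v))^2), numeric(1)))
}

#' @export
print.grade_assignment <- function(x, ...) {
  cat("Grade assignment (", x$method, ", k = ", x$k, ")\n", sep = "")
  cat("  breaks:", paste(signif(x$breaks, 6), collapse = ", "), "\n")
  print(table(grade = x$grades$grade))
  invisible(x)
}
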