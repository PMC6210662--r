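# Independent oracles and small fixture builders used across the suite.

# Matrix inverse by cofactor expansion, k <= 3 (independent of solve()).
inv_cofactor <- function(A) {
  k <- nrow(A)
  if (k == 1) return(matrix(1 / A[1, 1], 1, 1))
  if (k == 2) {
    d <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
    return(matrix(c(A[2, 2], -A[2, 1], -A[1, 2], A[1, 1]), 2) / d)
  }
  stopifnot(k == 3)
  cof <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    m <- A[-i, -j, drop = FALSE]
    cof[i, j] <- (-1)^(i + j) * (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])
  }
  d <- sum(A[1, ] * cof[1, ])
  t(cof) / d
}

# Brute-force scaled Mahalanobis distance for one vector, k <= 3.
md_oracle <- function(x, means, sds, corr, scale_by_k = TRUE) {
  z <- (x - means) / sds
  val <- as.numeric(t(z) %*% inv_cofactor(corr) %*% z)
  if (scale_by_k) val / length(z) else val
}

# Random correlation matrix of dimension k (positive definite).
random_corr <- function(k) {
  A <- crossprod(matrix(stats::rnorm((k + 3) * k), ncol = k))
  stats::cov2cor(A)
}

# Reference-space stand-in with hand-chosen statistics (for oracle checks
# that need full control over means/sds/corr).
make_ref <- function(means, sds, corr) {
  structure(list(variables = names(means), means = means, sds = sds,
                 corr = corr, corr_inv = solve(corr), pseudo = FALSE,
                 eigenvalues = eigen(corr, TRUE, TRUE)$values,
                 degenerate = character(0),
                 n_members = NA_integer_, member_cas = NULL),
            class = "reference_space")
}

# Weighted-kappa oracle: builds weight, observed and expected matrices
# explicitly with loops.
kappa_oracle <- function(tab, weighting) {
  k <- nrow(tab)
  o <- tab / sum(tab)
  rm <- rowSums(o)
  cm <- colSums(o)
  w <- matrix(0, k, k)
  for (i in 1:k) for (j in 1:k) {
    d <- abs(i - j)
    w[i, j] <- switch(weighting,
                      unweighted = as.numeric(d != 0),
                      linear = d / (k - 1),
                      quadratic = (d / (k - 1))^2)
  }
  num <- 0
  den <- 0
  for (i in 1:k) for (j in 1:k) {
    num <- num + w[i, j] * o[i, j]
    den <- den + w[i, j] * rm[i] * cm[j]
  }
  unname(1 - num / den)
}

# Exhaustive Jenks oracle: minimum within-class SSD over every contiguous
# partition of the sorted data into exactly k classes.
jenks_enum_ssd <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  ssd <- function(v) sum((v - mean(v))^2)
  cuts <- utils::combn(n - 1, k - 1)
  best <- Inf
  for (c_idx in seq_len(ncol(cuts))) {
    bounds <- c(0, cuts[, c_idx], n)
    total <- sum(vapply(seq_len(k), function(m) {
      ssd(x[(bounds[m] + 1):bounds[m + 1]])
    }, numeric(1)))
    best <- min(best, total)
  }
  best
}

# One record with the given category in one endpoint and a fill elsewhere.
record_with <- function(cas, variable = NULL, category = NULL,
                        fill = "NOT_CLASSIFIED") {
  df <- data.frame(cas = cas, name = cas, stringsAsFactors = FALSE)
  for (v in ghs_variables()) df[[v]] <- fill
  if (!is.null(variable)) df[[variable]] <- category
  df
}

# Random valid GHS record table (categories drawn per-endpoint from the
# labels defined for that endpoint).
random_records <- function(n, seed = 1) {
  set.seed(seed)
  df <- data.frame(cas = sprintf("RND-%04d", seq_len(n)),
                   name = sprintf("random %d", seq_len(n)),
                   stringsAsFactors = FALSE)
  for (v in ghs_variables()) {
    allowed <- mtshazard:::ghs_allowed_categories(v)
    df[[v]] <- sample(allowed, n, replace = TRUE)
  }
  as_ghs_records(df)
}

# Raw 12-column dialect fixture with messy category strings.
toy_raw_df <- function() {
  df <- data.frame(
    cas = c("50-00-0", "64-17-5", "71-43-2"),
    name = c("formaldehyde", "ethanol", "benzene"),
    stringsAsFactors = FALSE)
  raw_cols <- mtshazard:::ghs_raw_variables()
  for (v in raw_cols) df[[v]] <- "Not classified"
  df$acute_inhalation_gas <- c("2", "Not classified", "4")
  df$acute_inhalation_vapor <- c("4", "Not classified", "Not classified")
  df$carcinogenicity <- c("1A", "Not classified", "1B")
  df$mutagenicity <- c("Not classified", "Not classified", "1B")
  df
}
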