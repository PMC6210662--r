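# Pearson correlation, weighted kappa, regulatory validation, group summaries.

test_that("Pearson correlation matches the textbook formula", {
  x <- c(2, 4, 5, 7, 9)
  expect_equal(score_correlation(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(score_correlation(x, -x)$r, -1, tolerance = 1e-12)

  y <- c(1, 3, 2, 6, 8)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  got <- score_correlation(x, y)
  expect_equal(got$r, r_hand, tolerance = 1e-12)
  # two-sided t test with n - 2 df
  tstat <- r_hand * sqrt(3 / (1 - r_hand^2))
  expect_equal(got$p, 2 * stats::pt(-abs(tstat), df = 3), tolerance = 1e-12)

  expect_error(score_correlation(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(score_correlation(1:2, 2:3), "at least 3")
})

make_assignment <- function(grades, k = 4) {
  fr <- data.frame(cas = names(grades), score = as.numeric(grades),
                   grade = as.integer(grades), stringsAsFactors = FALSE)
  structure(list(method = "manual", k = as.integer(k),
                 breaks = seq_len(k - 1) + 0.5, grades = fr),
            class = "grade_assignment")
}

test_that("contingency tables count co-classifications", {
  a <- make_assignment(c(A = 1, B = 2, C = 3, D = 4))
  expect_equal(diag(grade_contingency(a, a)), rep(1, 4), ignore_attr = TRUE)
  expect_equal(sum(grade_contingency(a, a)), 4)

  b <- make_assignment(c(A = 2, B = 2, C = 3, D = 1))
  tab <- grade_contingency(a, b)
  expect_equal(tab[1, 2], 1)  # A: 1 vs 2
  expect_equal(tab[2, 2], 1)  # B agrees on 2
  expect_equal(tab[3, 3], 1)
  expect_equal(tab[4, 1], 1)  # D: 4 vs 1
  expect_equal(sum(tab), 4)

  d <- make_assignment(c(X = 1, Y = 2, Z = 3, W = 4))
  expect_error(grade_contingency(a, d), "differ")
})

test_that("weighted kappa reproduces hand computations and the oracle", {
  diag_tab <- diag(c(10, 20, 5, 8))
  for (w in c("unweighted", "linear", "quadratic"))
    expect_equal(weighted_kappa(diag_tab, w), 1)

  # hand-computed 2x2: p_o = 0.7, p_e = 0.5 -> kappa = 0.4
  expect_equal(weighted_kappa(matrix(c(20, 10, 5, 15), 2), "unweighted"), 0.4,
               tolerance = 1e-12)

  set.seed(55)
  for (trial in 1:30) {
    tab <- matrix(stats::rpois(16, 8), 4)
    for (w in c("unweighted", "linear", "quadratic"))
      expect_equal(weighted_kappa(tab, w), kappa_oracle(tab, w),
                   tolerance = 1e-10)
  }

  one_cell <- matrix(0, 3, 3)
  one_cell[2, 2] <- 12
  expect_warning(expect_equal(weighted_kappa(one_cell, "linear"), 1),
                 "no expected disagreement")
})

test_that("kappa is invariant under a shared order-preserving relabeling", {
  set.seed(60)
  g1 <- sample(1:4, 50, replace = TRUE)
  g2 <- pmin(pmax(g1 + sample(-1:1, 50, replace = TRUE), 1), 4)
  cas <- sprintf("K-%02d", 1:50)
  a <- make_assignment(stats::setNames(g1, cas))
  b <- make_assignment(stats::setNames(g2, cas))
  tab <- grade_contingency(a, b)
  # relabel both by the same monotone map 1,2,3,4 -> 1,2,3,4 reversed twice
  relab <- function(g) 5L - g
  a2 <- make_assignment(stats::setNames(relab(g1), cas))
  b2 <- make_assignment(stats::setNames(relab(g2), cas))
  tab2 <- grade_contingency(a2, b2)
  for (w in c("unweighted", "linear", "quadratic"))
    expect_equal(weighted_kappa(tab, w), weighted_kappa(tab2, w),
                 tolerance = 1e-12)
})

test_that("regulatory validation reproduces confusion-count proportions", {
  # 42 of 66 regulated and 10 of 74 non-regulated chemicals in grades 3-4
  reg <- sprintf("REG-%03d", 1:66)
  oth <- sprintf("OTH-%03d", 1:74)
  scores <- c(stats::setNames(c(rep(90, 42), rep(10, 24)), reg),
              stats::setNames(c(rep(80, 10), rep(5, 64)), oth))
  g <- classify_equal_interval(scores, k = 4)
  v <- regulatory_validation(g, reg)
  expect_equal(v$tp_count, 42)
  expect_equal(v$n_regulated, 66)
  expect_equal(round(100 * v$tp, 1), 63.6)
  expect_equal(v$fp_count, 10)
  expect_equal(round(100 * v$fp, 1), 13.5)
  # numerators over complementary sets sum to the high-grade set size
  high <- sum(g$grades$grade %in% c(3, 4))
  expect_equal(v$tp_count + v$fp_count, high)

  none <- regulatory_validation(g, reg[43:66])  # none of these in 3-4
  expect_equal(none$tp, 0)
  expect_error(regulatory_validation(g, character(0)), "empty")
  expect_warning(regulatory_validation(g, c(reg, "UNSEEN-1")), "not in")
})

test_that("group summaries use Student-t intervals and flag singletons", {
  sc <- stats::setNames(c(5, 5, 5, 1, 2, 3, 9), sprintf("G-%d", 1:7))
  groups <- stats::setNames(c("a", "a", "a", "b", "b", "b", "c"),
                            names(sc))
  out <- group_summary(sc, groups)
  a_row <- out[out$group == "a", ]
  expect_equal(a_row$mean, 5)
  expect_equal(a_row$ci_lower, a_row$ci_upper)   # zero-width interval

  b_row <- out[out$group == "b", ]
  expect_equal(b_row$mean, 2)
  # frozen t quantile: qt(0.975, 2) = 4.30265272974946
  half <- 4.30265272974946 / sqrt(3)
  expect_equal(b_row$ci_lower, 2 - half, tolerance = 1e-10)
  expect_equal(b_row$ci_upper, 2 + half, tolerance = 1e-10)

  c_row <- out[out$group == "c", ]
  expect_equal(c_row$n, 1)
  expect_true(is.na(c_row$ci_lower))

  # chemicals without a label fall into "other"
  out2 <- group_summary(sc, groups[1:5])
  expect_true("other" %in% out2$group)
  expect_equal(out2$n[out2$group == "other"], 2)
})

test_that("agreement report combines correlation and kappas consistently", {
  set.seed(77)
  cas <- sprintf("C-%03d", 1:120)
  x <- stats::setNames(stats::rlnorm(120, 2, 0.7), cas)
  y <- stats::setNames(unname(x) * stats::rlnorm(120, 0, 0.4), cas)
  rep <- agreement_report(x, y, method = "quantile", k = 4)
  expect_equal(rep$pearson_r, score_correlation(unname(x), unname(y))$r)
  tab <- rep$contingency
  expect_equal(rep$kappa_quadratic, kappa_oracle(tab, "quadratic"),
               tolerance = 1e-12)
  expect_equal(sum(tab), 120)
  # near-monotone tables: kappa tends to grow with the weighting degree
  expect_gte(rep$kappa_quadratic, rep$kappa_unweighted)
})
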