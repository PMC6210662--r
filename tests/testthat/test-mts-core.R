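# Unit-space construction and scaled Mahalanobis distances.

test_that("normal-group selection applies the low-hazard criteria", {
  filler <- lapply(1:15, function(i) record_with(sprintf("F-%02d", i)))
  df <- do.call(rbind, c(list(
    as.data.frame(fixture_flutolanil()),
    record_with("HAS-CAT1", "carcinogenicity", "CAT1",
                fill = "NOT_APPLICABLE"),
    record_with("ALL-CNP", fill = "CLASSIFICATION_NOT_POSSIBLE")),
    filler))
  rec <- as_ghs_records(df)
  members <- select_normal_group(rec)
  expect_true("66332-96-5" %in% members)     # flutolanil, total 120
  expect_false("HAS-CAT1" %in% members)      # one Category 1, total 109
  expect_false("ALL-CNP" %in% members)       # total 300 > 280
})

test_that("total-score ceiling is inclusive by default and configurable", {
  base <- lapply(1:13, function(i) record_with(sprintf("B-%02d", i)))
  # exactly 280 points: 7 CNP (210) + CAT5 (20) + 2 CAT4 (50)
  exact <- record_with("EXACT-280", fill = "CLASSIFICATION_NOT_POSSIBLE")
  exact$acute_oral <- "CAT5"
  exact[c("acute_dermal", "acute_inhalation")] <- "CAT4"
  rec <- as_ghs_records(do.call(rbind, c(base, list(exact))))
  expect_equal(ghs_quantify(rec)$total[rec$cas == "EXACT-280"], 280)
  expect_true("EXACT-280" %in% select_normal_group(rec))
  strict <- selection_criteria(inclusive = FALSE)
  expect_false("EXACT-280" %in%
                 select_normal_group(rec, criteria = strict))
})

test_that("too small a candidate group is fatal with guidance", {
  rec <- as_ghs_records(do.call(rbind, lapply(1:5, function(i)
    record_with(sprintf("S-%02d", i)))))
  expect_error(select_normal_group(rec), "relax")
})

test_that("reference fit matches textbook statistics on a controlled toy", {
  set.seed(7)
  n <- 20
  a <- stats::rnorm(n, 30, 6)
  b <- 0.6 * a + stats::rnorm(n, 10, 4)
  df <- data.frame(cas = sprintf("T-%02d", 1:n))
  for (v in ghs_variables()) df[[v]] <- 10        # constant -> degenerate
  df$acute_oral <- a
  df$skin_corrosion <- b
  ref <- suppressWarnings(fit_reference(df))
  expect_setequal(ref$degenerate,
                  setdiff(ghs_variables(), c("acute_oral", "skin_corrosion")))
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(ref$corr["acute_oral", "skin_corrosion"], r_hand,
               tolerance = 1e-12)
  expect_equal(unname(ref$means["acute_oral"]), mean(a), tolerance = 1e-12)
  expect_equal(unname(ref$sds["skin_corrosion"]), stats::sd(b),
               tolerance = 1e-12)
  # inverse and pseudoinverse contract
  expect_equal(ref$corr %*% ref$corr_inv %*% ref$corr, ref$corr,
               tolerance = 1e-8)
})

test_that("distance is zero at the centre and matches closed forms", {
  means <- c(v1 = 10, v2 = 20)
  sds <- c(v1 = 2, v2 = 5)
  ref_id <- make_ref(means, sds, diag(2))
  centre <- matrix(means, 1, dimnames = list("c", c("v1", "v2")))
  expect_equal(unname(mahalanobis_distance(centre, ref_id)), 0)

  # standardized deviations z = (3, 4), identity correlation: (9+16)/2
  x <- matrix(means + c(3, 4) * sds, 1, dimnames = list("x", c("v1", "v2")))
  expect_equal(unname(mahalanobis_distance(x, ref_id)), 12.5)

  # correlation 0.5, z = (1, 1): closed-form 2x2 inverse gives 2/3
  ref_r <- make_ref(means, sds, matrix(c(1, 0.5, 0.5, 1), 2))
  y <- matrix(means + sds, 1, dimnames = list("y", c("v1", "v2")))
  expect_equal(unname(mahalanobis_distance(y, ref_r)), 2 / 3,
               tolerance = 1e-12)
})

test_that("distance agrees with a cofactor-inversion oracle on random instances", {
  set.seed(99)
  for (trial in 1:40) {
    k <- sample(1:3, 1)
    vars <- paste0("v", seq_len(k))
    means <- stats::setNames(stats::rnorm(k, 20, 5), vars)
    sds <- stats::setNames(stats::runif(k, 0.5, 4), vars)
    corr <- if (k == 1) matrix(1, 1, 1) else random_corr(k)
    ref <- make_ref(means, sds, corr)
    x <- means + stats::rnorm(k, 0, 3)
    xm <- matrix(x, 1, dimnames = list("x", vars))
    expect_equal(unname(mahalanobis_distance(xm, ref)),
                 md_oracle(x, means, sds, corr), tolerance = 1e-10)
    # cross-check against stats::mahalanobis on the standardized scale
    z <- (x - means) / sds
    expect_equal(unname(mahalanobis_distance(xm, ref, scale_by_k = FALSE)),
                 unname(stats::mahalanobis(rbind(z), rep(0, k), corr)),
                 tolerance = 1e-10)
  }
})

test_that("unit-space members average (n-1)/n in scaled distance", {
  sim <- simulate_ghs(simulation_config(n_chemicals = 600, n_planted = 0,
                                        seed = 12))
  scores <- ghs_quantify(sim$records)
  members <- select_normal_group(sim$records, scores)
  ref <- fit_reference(scores[scores$cas %in% members, ])
  expect_false(ref$pseudo)
  md <- mahalanobis_distance(scores[scores$cas %in% members, ], ref)
  n <- ref$n_members
  expect_equal(mean(md), (n - 1) / n, tolerance = 1e-8)
})

test_that("distance is invariant under endpoint reordering", {
  sim <- simulate_ghs(simulation_config(n_chemicals = 300, n_planted = 0,
                                        seed = 4))
  scores <- ghs_quantify(sim$records)
  members <- select_normal_group(sim$records, scores)
  ref <- fit_reference(scores[scores$cas %in% members, ])
  m <- mtshazard:::score_matrix(scores)
  perm <- sample(ncol(m))
  expect_equal(mahalanobis_distance(m, ref),
               mahalanobis_distance(m[, perm], ref), tolerance = 1e-12)
})

test_that("ranking puts an all-Category-1 record first and handles ties", {
  sim <- simulate_ghs(simulation_config(n_chemicals = 300, n_planted = 0,
                                        seed = 8))
  extreme <- as_ghs_records(record_with("EXTREME", fill = "CAT1"))
  rec <- as_ghs_records(rbind(as.data.frame(sim$records),
                              as.data.frame(extreme)))
  scores <- ghs_quantify(rec)
  members <- select_normal_group(rec, scores)
  ref <- fit_reference(scores[scores$cas %in% members, ])
  rk <- mahalanobis_score(scores, ref)
  expect_equal(rk$rank[rk$cas == "EXTREME"], 1L)

  # identical records tie with competition ranks, next rank skipped
  dup <- scores[rep(which(scores$cas == "EXTREME"), 2), ]
  dup$cas <- c("DUP-1", "DUP-2")
  rk2 <- mahalanobis_score(rbind(scores, dup), ref)
  top <- rk2[rk2$cas %in% c("EXTREME", "DUP-1", "DUP-2"), ]
  expect_true(all(top$rank == 1L))
  expect_equal(min(rk2$rank[!rk2$cas %in% top$cas]), 4L)

  # permuting input order leaves the cas -> (md, rank) map unchanged
  shuf <- scores[sample(nrow(scores)), ]
  rk3 <- mahalanobis_score(shuf, ref)
  rk3 <- rk3[match(rk$cas, rk3$cas), ]
  expect_equal(rk3$md, rk$md)
  expect_equal(rk3$rank, rk$rank)
})

test_that("injected high-hazard endpoints raise expected distance", {
  set.seed(2024)
  deltas <- replicate(25, {
    seed <- sample.int(1e6, 1)
    sim <- simulate_ghs(simulation_config(n_chemicals = 250, n_planted = 0,
                                          seed = seed))
    rec <- as.data.frame(sim$records)
    boosted <- rec[1:20, ]
    boosted$cas <- paste0("BOOST-", seq_len(nrow(boosted)))
    for (v in c("carcinogenicity", "mutagenicity", "acute_oral"))
      boosted[[v]] <- "CAT1"
    all_rec <- as_ghs_records(rbind(rec, boosted))
    scores <- ghs_quantify(all_rec)
    members <- select_normal_group(all_rec, scores)
    ref <- fit_reference(scores[scores$cas %in% members, ])
    md <- mahalanobis_distance(scores, ref)
    mean(md[boosted$cas]) - mean(md[rec$cas[1:20]])
  })
  expect_true(mean(deltas) > 0)
  expect_true(mean(deltas > 0) > 0.9)
})

test_that("reference serialization retains full-precision statistics", {
  sim <- simulate_ghs(simulation_config(n_chemicals = 250, n_planted = 0,
                                        seed = 2))
  scores <- ghs_quantify(sim$records)
  ref <- fit_reference(scores[scores$cas %in%
                                select_normal_group(sim$records, scores), ])
  parsed <- jsonlite::fromJSON(reference_json(ref))
  expect_equal(parsed$n_members, ref$n_members)
  expect_equal(unlist(parsed$means), ref$means, tolerance = 1e-12)
  expect_equal(parsed$corr, unname(ref$corr) * 1, tolerance = 1e-12,
               ignore_attr = TRUE)
})
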