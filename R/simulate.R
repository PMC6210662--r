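# Synthetic GHS hazard tables: latent-Gaussian severities discretized into
# endpoint categories, with missing-information masking and planted
# high-hazard chemicals, so the whole scoring pipeline is testable without
# any external dataset.

# Marginal category probabilities per endpoint, from least to most severe
# (Not Classified first, then the numbered categories from the endpoint's
# weakest up to Category 1). Calibrated so ~5% of background cells fall in
# Category 1 or 2, keeping a usable low-hazard normal group.
default_category_probs <- function() {
  acute <- c(NOT_CLASSIFIED = 0.60, CAT5 = 0.12, CAT4 = 0.12, CAT3 = 0.11,
             CAT2 = 0.04, CAT1 = 0.01)
  binary <- c(NOT_CLASSIFIED = 0.95, CAT2 = 0.04, CAT1 = 0.01)
  stot1 <- c(NOT_CLASSIFIED = 0.88, CAT3 = 0.07, CAT2 = 0.04, CAT1 = 0.01)
  list(acute_oral = acute, acute_dermal = acute, acute_inhalation = acute,
       skin_corrosion = binary, eye_damage = binary,
       mutagenicity = binary, carcinogenicity = binary, reproductive = binary,
       stot_single = stot1, stot_repeated = binary)
}

#' Default latent correlation between endpoint severities
#'
#' A 10 x 10 correlation matrix emulating the empirically strong endpoint
#' associations in curated GHS tables: skin/eye irritation r = 0.70, acute
#' oral/dermal r = 0.60, the two STOT endpoints r = 0.53, plus weaker
#' associations among the acute routes and the CMR endpoints; all remaining
#' pairs uncorrelated.
#'
#' @return Symmetric positive-definite 10 x 10 matrix with unit diagonal,
#'   dimnames \code{ghs_variables()}.
#' @export
default_latent_corr <- function() {
  v <- ghs_variables()
  m <- diag(length(v))
  dimnames(m) <- list(v, v)
  set_pair <- function(a, b, r) {
    m[a, b] <<- r
    m[b, a] <<- r
  }
  set_pair("skin_corrosion", "eye_damage", 0.70)
  set_pair("acute_oral", "acute_dermal", 0.60)
  set_pair("stot_single", "stot_repeated", 0.53)
  set_pair("acute_oral", "acute_inhalation", 0.28)
  set_pair("acute_dermal", "acute_inhalation", 0.25)
  set_pair("mutagenicity", "carcinogenicity", 0.37)
  set_pair("carcinogenicity", "reproductive", 0.32)
  set_pair("mutagenicity", "reproductive", 0.25)
  set_pair("carcinogenicity", "skin_corrosion", 0.25)
  set_pair("stot_single", "acute_oral", 0.22)
  set_pair("stot_single", "acute_inhalation", 0.27)
  m
}

#' Configuration of the synthetic GHS table generator
#'
#' @param n_chemicals Number of background chemicals (default 3000).
#' @param latent_corr Target 10 x 10 correlation of the latent severity
#'   scale; must be symmetric positive semi-definite.
#' @param category_probs Per-endpoint named list of marginal category
#'   probabilities, least-severe first (converted internally to ascending
#'   standard-normal thresholds).
#' @param p_cnp Probability that a cell is masked to Classification Not
#'   Possible (default 0.15, mimicking widespread data gaps).
#' @param p_na Probability of a Not Applicable mask (default 0.05).
#' @param n_planted Number of planted high-severity chemicals appended to
#'   the background (default 10).
#' @param seed Integer RNG seed; recorded in the output metadata.
#' @return List of class \code{simulation_config}.
#' @export
simulation_config <- function(n_chemicals = 3000,
                              latent_corr = default_latent_corr(),
                              category_probs = default_category_probs(),
                              p_cnp = 0.15, p_na = 0.05,
                              n_planted = 10, seed = 1L) {
  stopifnot(n_chemicals > 0, p_cnp >= 0, p_cnp <= 1, p_na >= 0, p_na <= 1,
            p_cnp + p_na <= 1, n_planted >= 0)
  latent_corr <- as.matrix(latent_corr)
  if (!isTRUE(all.equal(latent_corr, t(latent_corr))))
    stop("latent_corr must be symmetric", call. = FALSE)
  ev <- eigen(latent_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("latent_corr is not positive semi-definite (smallest eigenvalue ",
         signif(min(ev), 4), ")", call. = FALSE)
  stopifnot(setequal(names(category_probs), ghs_variables()))
  for (v in ghs_variables()) {
    p <- category_probs[[v]]
    stopifnot(abs(sum(p) - 1) < 1e-8, all(p > 0))
  }
  structure(list(n_chemicals = as.integer(n_chemicals),
                 latent_corr = latent_corr,
                 category_probs = category_probs,
                 p_cnp = p_cnp, p_na = p_na,
                 n_planted = as.integer(n_planted),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Ascending thresholds on the latent N(0,1) scale for one endpoint.
latent_thresholds <- function(probs) {
  stats::qnorm(cumsum(probs)[-length(probs)])
}

#' Generate a synthetic GHS hazard table
#'
#' Draws zero-mean correlated Gaussian latent severities (Cholesky factor of
#' \code{latent_corr}), discretizes each cell through its endpoint's
#' thresholds into the categories defined for that endpoint, applies
#' independent Classification Not Possible / Not Applicable masking, and
#' appends \code{n_planted} planted hazards forced to Category 1 on at least
#' six randomly chosen endpoints. Fully reproducible given the seed.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return List of class \code{ghs_simulation}: \code{records} (a
#'   \code{ghs_records} table), \code{truth} (data frame \code{cas},
#'   \code{planted}), \code{config}.
#' @export
simulate_ghs <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  vars <- ghs_variables()
  n <- config$n_chemicals + config$n_planted
  L <- chol(config$latent_corr + diag(1e-12, length(vars)))
  z <- matrix(stats::rnorm(n * length(vars)), nrow = n) %*% L
  colnames(z) <- vars

  cells <- matrix("", nrow = n, ncol = length(vars),
                  dimnames = list(NULL, vars))
  for (v in vars) {
    p <- config$category_probs[[v]]
    cells[, v] <- names(p)[findInterval(z[, v], latent_thresholds(p)) + 1L]
  }
  # independent missing-information masking
  u <- matrix(stats::runif(n * length(vars)), nrow = n)
  cells[u < config$p_cnp] <- "CLASSIFICATION_NOT_POSSIBLE"
  cells[u >= config$p_cnp & u < config$p_cnp + config$p_na] <- "NOT_APPLICABLE"

  planted <- rep(FALSE, n)
  if (config$n_planted > 0) {
    idx <- config$n_chemicals + seq_len(config$n_planted)
    planted[idx] <- TRUE
    for (i in idx) {
      n_force <- sample(6:8, 1)
      force_vars <- sample(vars, n_force)
      cells[i, force_vars] <- "CAT1"
    }
  }

  df <- data.frame(cas = sprintf("SIM-%06d", seq_len(n)),
                   name = sprintf("synthetic chemical %d", seq_len(n)),
                   cells, stringsAsFactors = FALSE)
  records <- as_ghs_records(df)
  structure(list(records = records,
                 truth = data.frame(cas = df$cas, planted = planted,
                                    stringsAsFactors = FALSE),
                 config = config),
            class = "ghs_simulation")
}

#' Write a simulation to disk
#'
#' CSV in the reader's aggregated dialect plus a JSON ground-truth sidecar
#' (planted flags and the generator seed).
#'
#' @param sim A \code{ghs_simulation}.
#' @param csv_path,truth_path Output paths.
#' @return \code{csv_path}, invisibly.
#' @export
write_simulation <- function(sim, csv_path, truth_path = NULL) {
  stopifnot(inherits(sim, "ghs_simulation"))
  write_ghs_table(sim$records, csv_path)
  if (!is.null(truth_path)) {
    payload <- list(seed = sim$config$seed,
                    n_chemicals = sim$config$n_chemicals,
                    n_planted = sim$config$n_planted,
                    planted_cas = sim$truth$cas[sim$truth$planted])
    writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE), truth_path)
  }
  invisible(csv_path)
}

#' Worked low-hazard example record: flutolanil
#'
#' Flutolanil (CAS 66332-96-5) carries nine Not Classified endpoints and one
#' Classification Not Possible, so its quantified total is
#' 9 x 10 + 30 = 120 points and it qualifies for the default low-hazard
#' normal group.
#'
#' @return A one-row \code{ghs_records} table.
#' @export
fixture_flutolanil <- function() {
  df <- data.frame(cas = "66332-96-5", name = "flutolanil",
                   stringsAsFactors = FALSE)
  for (v in ghs_variables()) df[[v]] <- "NOT_CLASSIFIED"
  df$acute_inhalation <- "CLASSIFICATION_NOT_POSSIBLE"
  as_ghs_records(df)
}

#' Ten extreme high-hazard reference profiles
#'
#' Category profiles of ten classic highly hazardous substances (mustard
#' gas, mechlorethamine, aziridine, sodium dichromate, diethyl sulfate,
#' chloromethyl methyl ether, phenol, captafol, 1,4-dichloro-2-butene,
#' dieldrin), dominated by Category 1/2 classifications. Useful as planted
#' extremes: none qualifies for the low-hazard normal group, and all rank
#' far from a low-hazard unit space.
#'
#' @return A ten-row \code{ghs_records} table.
#' @export
fixture_table5 <- function() {
  rows <- list(
    list("505-60-2", "bis(2-chloroethyl)sulfide",
         c("CAT2", "CAT1", "CAT1", "CAT1", "CAT1",
           "CAT1", "CAT1", "CAT1", "CAT2", "CAT1")),
    list("51-75-2", "bis(2-chloroethyl)methylamine",
         c("CAT2", "CAT1", "CAT1", "CAT1", "CAT1",
           "CAT1", "CAT1", "CLASSIFICATION_NOT_POSSIBLE", "CAT1",
           "CLASSIFICATION_NOT_POSSIBLE")),
    list("151-56-4", "aziridine",
         c("CAT2", "CAT1", "CAT1", "CAT1", "CAT1",
           "CAT1", "CAT2", "CAT2", "CAT1", "CAT1")),
    list("10588-01-9", "sodium dichromate",
         c("CAT3", "CAT3", "CAT2", "CAT1", "CAT1",
           "CAT2", "CAT1", "NOT_CLASSIFIED", "CAT1", "CAT1")),
    list("64-67-5", "diethyl sulfate",
         c("CAT4", "CAT3", "CLASSIFICATION_NOT_POSSIBLE", "CAT1", "CAT1",
           "CAT1", "CAT1", "CLASSIFICATION_NOT_POSSIBLE", "CAT2",
           "CLASSIFICATION_NOT_POSSIBLE")),
    list("107-30-2", "chloromethyl methyl ether",
         c("CAT4", "CLASSIFICATION_NOT_POSSIBLE", "CAT1", "CAT1", "CAT1",
           "CAT2", "CAT1", "CLASSIFICATION_NOT_POSSIBLE", "CAT1",
           "CLASSIFICATION_NOT_POSSIBLE")),
    list("108-95-2", "phenol",
         c("CAT4", "CAT3", "CLASSIFICATION_NOT_POSSIBLE", "CAT1", "CAT1",
           "CAT1", "NOT_CLASSIFIED", "CAT1", "CAT1", "CAT1")),
    list("2425-06-1", "captafol",
         c("CAT5", "NOT_CLASSIFIED", "CLASSIFICATION_NOT_POSSIBLE", "CAT2",
           "CAT2", "CAT1", "CAT1", "NOT_CLASSIFIED",
           "CLASSIFICATION_NOT_POSSIBLE", "CAT1")),
    list("764-41-0", "1,4-dichloro-2-butene",
         c("CAT3", "CAT3", "CAT1", "CAT1", "CAT1",
           "CAT2", "CAT1", "CLASSIFICATION_NOT_POSSIBLE", "CAT1", "CAT1")),
    list("60-57-1", "dieldrin",
         c("CAT1", "CAT1", "CAT1", "CLASSIFICATION_NOT_POSSIBLE",
           "CLASSIFICATION_NOT_POSSIBLE", "NOT_CLASSIFIED",
           "NOT_CLASSIFIED", "CAT1", "CAT1", "CAT1")))
  df <- data.frame(cas = vapply(rows, `[[`, "", 1),
                   name = vapply(rows, `[[`, "", 2),
                   stringsAsFactors = FALSE)
  cats <- t(vapply(rows, `[[`, character(10), 3))
  colnames(cats) <- ghs_variables()
  as_ghs_records(cbind(df, cats))
}
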