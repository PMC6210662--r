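# End-to-end pipeline: simulate/ingest -> quantify -> unit space -> score ->
# grade -> agreement/validation, writing every intermediate artifact plus a
# run manifest.

#' Read a pipeline run configuration
#'
#' YAML or JSON file holding any of the fields accepted by
#' \code{\link{run_pipeline}} (\code{input}, \code{simulate},
#' \code{scheme_overrides}, \code{criteria}, \code{grading},
#' \code{external_scores}, \code{regulated_list}, \code{out_dir},
#' \code{seed}).
#'
#' @param path Path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
}

#' Run the full hazard-ranking pipeline
#'
#' Chains the stages: read (or simulate) a GHS table, quantify categories,
#' select the low-hazard normal group, fit the unit space, score every
#' chemical by scaled Mahalanobis distance, grade the distances, and --
#' when external scores or a regulated list are supplied -- compute
#' agreement and validation reports. Every intermediate artifact is written
#' under \code{out_dir} together with a manifest of stage counts.
#'
#' @param config Named list (or path consumed by
#'   \code{\link{read_run_config}}) with fields: \code{input} (CSV path) or
#'   \code{simulate} (list of \code{\link{simulation_config}} arguments);
#'   \code{scheme_overrides} (named category-score overrides);
#'   \code{criteria} (list of \code{\link{selection_criteria}} arguments);
#'   \code{grading} (list with \code{method}, \code{k});
#'   \code{external_scores} (named list of CSV paths with columns
#'   \code{cas}, \code{score}); \code{regulated_list} (path);
#'   \code{out_dir}; \code{seed}.
#' @param quiet Suppress progress messages.
#' @return The manifest, invisibly: list with stage counts, paths and the
#'   configuration echo.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1)
    config <- read_run_config(config)
  stopifnot(is.list(config))
  out_dir <- config$out_dir %||% stop("config must name an out_dir",
                                      call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[mtshazard] ", ...)

  scheme <- quantification_scheme(overrides = unlist(config$scheme_overrides))

  # stage 1: input
  if (!is.null(config$input)) {
    say("reading ", config$input)
    records <- read_ghs_table(config$input, scheme = scheme)
    log <- attr(records, "io_log")
    truth <- NULL
  } else {
    sim_args <- config$simulate %||% list()
    if (!is.null(config$seed) && is.null(sim_args$seed))
      sim_args$seed <- config$seed
    if (!is.null(sim_args$latent_corr))
      sim_args$latent_corr <- as.matrix(sim_args$latent_corr)
    sim <- simulate_ghs(do.call(simulation_config, sim_args))
    say("simulated ", nrow(sim$records), " chemicals (seed ",
        sim$config$seed, ")")
    records <- sim$records
    truth <- sim$truth
    write_simulation(sim, file.path(out_dir, "simulated_records.csv"),
                     file.path(out_dir, "simulated_truth.json"))
    log <- list(n_read = nrow(records), n_dropped_no_cas = 0L,
                n_deduplicated = 0L, n_kept = nrow(records))
  }

  # stage 2: quantification
  scores <- ghs_quantify(records, scheme)
  write_score_table(scores, file.path(out_dir, "scores.csv"))

  # stage 3: unit space
  criteria <- do.call(selection_criteria, as.list(config$criteria %||% list()))
  members <- select_normal_group(records, scores, criteria)
  ref <- fit_reference(scores[scores$cas %in% members, ])
  say("unit space: ", ref$n_members, " members")
  reference_json(ref, file.path(out_dir, "reference.json"))

  # stage 4: Mahalanobis scoring
  ranking <- mahalanobis_score(scores, ref)
  utils::write.csv(as.data.frame(ranking),
                   file.path(out_dir, "md_ranking.csv"), row.names = FALSE)

  # stage 5: grading
  grading <- config$grading %||% list()
  method <- grading$method %||% "jenks"
  k <- grading$k %||% 4
  md_vec <- stats::setNames(ranking$md, ranking$cas)
  grades <- classify_scores(md_vec, method = method, k = k)
  gdf <- grades$grades
  utils::write.csv(gdf, file.path(out_dir, "grades.csv"), row.names = FALSE)
  writeLines(jsonlite::toJSON(list(method = grades$method, k = grades$k,
                                   breaks = grades$breaks),
                              auto_unbox = TRUE, digits = NA),
             file.path(out_dir, "grade_breaks.json"))

  # stage 6: agreement / validation (optional)
  reports <- list()
  for (nm in names(config$external_scores %||% list())) {
    ext <- utils::read.csv(config$external_scores[[nm]],
                           stringsAsFactors = FALSE)
    stopifnot(all(c("cas", "score") %in% names(ext)))
    rep <- agreement_report(md_vec,
                            stats::setNames(ext$score, ext$cas),
                            method = method, k = k)
    reports[[paste0("agreement_", nm)]] <-
      rep[c("pearson_r", "pearson_p", "kappa_unweighted", "kappa_linear",
            "kappa_quadratic", "n")]
  }
  if (!is.null(config$regulated_list)) {
    reg <- read_regulated_list(config$regulated_list)
    val <- regulatory_validation(grades, reg)
    reports$validation <- val[c("tp", "fp", "tp_count", "fp_count",
                                "n_regulated", "n_unregulated")]
  }
  if (length(reports) > 0)
    writeLines(jsonlite::toJSON(reports, auto_unbox = TRUE, digits = NA),
               file.path(out_dir, "reports.json"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("mtshazard")),
    seed = config$seed %||% (config$simulate$seed %||% NA),
    counts = c(log, list(normal_group_size = ref$n_members,
                         n_scored = nrow(ranking),
                         n_graded = nrow(gdf))),
    grading = list(method = method, k = k, breaks = grades$breaks),
    degenerate_endpoints = ref$degenerate,
    planted_cas = if (!is.null(truth)) truth$cas[truth$planted],
    artifacts = list.files(out_dir))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              null = "null"),
             file.path(out_dir, "manifest.json"))
  say("done: ", out_dir)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
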