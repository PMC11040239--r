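#' Read and validate a participant-object trial table
#'
#' Reads the long-format records CSV (UTF-8, comma-separated, header row; one
#' row per participant x object) and validates the schema: required columns
#' present, binary fields in \{0, 1\} (violations reported with row numbers),
#' `times_sampled` in 0..3 and summing to 3 per participant. An empty file
#' with only a header yields an empty table; downstream stages refuse it
#' with "no participants".
#'
#' @param path path to `records.csv`.
#' @return validated data.frame of records.
#' @export
read_trial_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "age_group", "object_id", "knowledge_judgement",
            "times_sampled", "test_correct", "confidence_rating")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop(sprintf("records file is missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  if (nrow(d) == 0L) return(d)
  for (col in c("knowledge_judgement", "test_correct", "confidence_rating")) {
    bad <- which(!d[[col]] %in% c(0L, 1L))
    if (length(bad)) {
      stop(sprintf("non-binary value in '%s' at row(s): %s", col,
                   paste(utils::head(bad, 10), collapse = ", ")), call. = FALSE)
    }
  }
  bad <- which(!d$times_sampled %in% 0:3)
  if (length(bad)) {
    stop(sprintf("times_sampled outside 0..3 at row(s): %s",
                 paste(utils::head(bad, 10), collapse = ", ")), call. = FALSE)
  }
  sums <- tapply(d$times_sampled, d$participant_id, sum)
  off <- names(sums)[sums != 3L]
  if (length(off)) {
    stop(sprintf("times_sampled does not sum to 3 for participant(s): %s",
                 paste(off, collapse = ", ")), call. = FALSE)
  }
  d
}

#' Read and validate a control-trial table
#'
#' @param path path to `controls.csv` (columns `participant_id`, `item_id`,
#'   `item_class` in \{familiar, unfamiliar\}, `judged_known` in \{0, 1\}).
#' @return validated data.frame of control trials.
#' @export
read_control_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "item_id", "item_class", "judged_known")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop(sprintf("controls file is missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  if (nrow(d) == 0L) return(d)
  bad <- which(!d$item_class %in% c("familiar", "unfamiliar"))
  if (length(bad)) {
    stop(sprintf("item_class must be familiar/unfamiliar; bad row(s): %s",
                 paste(utils::head(bad, 10), collapse = ", ")), call. = FALSE)
  }
  bad <- which(!d$judged_known %in% c(0L, 1L))
  if (length(bad)) {
    stop(sprintf("non-binary value in 'judged_known' at row(s): %s",
                 paste(utils::head(bad, 10), collapse = ", ")), call. = FALSE)
  }
  d
}

#' Configuration of an end-to-end pipeline run
#'
#' Exactly one data source must be supplied: either paths to the two CSVs
#' (`records_path` + `controls_path`) or a [simulation_config()]. All
#' randomness (simulation, permutations, bootstrap) flows from the single
#' master `seed` via named substreams, so stages can be re-run in isolation.
#'
#' @param records_path,controls_path CSV paths (deposited or previously
#'   simulated data).
#' @param simulation a `uds_config`, to simulate instead of reading files.
#' @param groups age groups to analyse (`NULL` = all groups in the data).
#' @param n_perm permutations for the sampling test (default 1000, observed
#'   data included).
#' @param n_boot parametric-bootstrap replicates for fitted-probability
#'   intervals (default 1000; 0 skips the bootstrap).
#' @param seed master seed; required whenever any stochastic stage runs.
#' @param exclusion_threshold minimum control score for inclusion, default 5.
#' @param verbose print stage progress.
#' @return an object of class `uds_pipeline_config`.
#' @export
pipeline_config <- function(records_path = NULL, controls_path = NULL,
                            simulation = NULL, groups = NULL,
                            n_perm = 1000, n_boot = 1000, seed = NULL,
                            exclusion_threshold = 5L, verbose = FALSE) {
  has_paths <- !is.null(records_path) || !is.null(controls_path)
  if (has_paths && is.null(controls_path)) {
    stop("controls_path is required together with records_path", call. = FALSE)
  }
  if (has_paths == !is.null(simulation)) {
    stop("supply exactly one of (records_path + controls_path) or simulation",
         call. = FALSE)
  }
  if (!is.null(simulation) && !inherits(simulation, "uds_config")) {
    stop("simulation must be a simulation_config() object", call. = FALSE)
  }
  if (is.null(seed)) stop("a master seed is required", call. = FALSE)
  structure(list(records_path = records_path, controls_path = controls_path,
                 simulation = simulation, groups = groups,
                 n_perm = n_perm, n_boot = n_boot, seed = as.integer(seed),
                 exclusion_threshold = as.integer(exclusion_threshold),
                 verbose = isTRUE(verbose)),
            class = "uds_pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Loads (or simulates) the data, applies the control-score exclusion
#' filter, then runs the seven analyses per age group: overall accuracy vs
#' chance, confidence-accuracy calibration, preferential sampling (with the
#' within-participant permutation test), the chance-corrected beta
#' regression, both sampling-benefit constructions (preregistered and
#' post-hoc), and the sampling x judgement interaction model. A failing
#' stage is recorded and the remaining stages continue; the bundle marks
#' partial completion.
#'
#' @param config a [pipeline_config()].
#' @return a `uds_bundle`: `reports[[group]][[analysis]]`, `exclusions`
#'   (control scores and excluded ids), `errors` (stage -> condition
#'   message), `fingerprint` (package version, seed, key settings),
#'   `complete` flag.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "uds_pipeline_config"))
  say <- function(...) if (config$verbose) message(sprintf(...))

  if (!is.null(config$simulation)) {
    say("simulating experiment (seed %d)", config$simulation$seed)
    data <- simulate_experiment(config$simulation)
    records <- data$records
    controls <- data$controls
  } else {
    records <- read_trial_table(config$records_path)
    controls <- read_control_table(config$controls_path)
  }
  if (nrow(records) == 0L) stop("no participants in the records table", call. = FALSE)

  excl <- score_controls_and_exclude(controls, config$exclusion_threshold)
  records_in <- records[records$participant_id %in% excl$included, , drop = FALSE]
  say("exclusion filter: %d of %d participants retained",
      length(excl$included), nrow(excl$scores))

  groups <- config$groups %||% unique(records$age_group)
  analyses <- c("overall_accuracy", "confidence_accuracy",
                "preferential_sampling", "chance_corrected_beta",
                "sampling_accuracy_preregistered", "sampling_accuracy_posthoc",
                "sampling_interaction")
  reports <- list()
  errors <- list()
  for (g in groups) {
    say("analysing group '%s'", g)
    reports[[g]] <- list()
    if (!g %in% records_in$age_group) {
      for (a in analyses) errors[[paste(g, a, sep = "/")]] <- "no data for this group"
      reports[[g]] <- stats::setNames(rep(list(NULL), length(analyses)), analyses)
      next
    }
    is_adult <- identical(g, "adult")
    run_stage <- function(analysis, expr) {
      res <- tryCatch(expr, error = function(e) {
        errors[[paste(g, analysis, sep = "/")]] <<- conditionMessage(e)
        NULL
      })
      reports[[g]][[analysis]] <<- res
    }
    run_stage("overall_accuracy", run_overall_accuracy(records_in, g))
    run_stage("confidence_accuracy",
              run_confidence_accuracy(records_in, g,
                                      include_random_slopes = !is_adult,
                                      n_boot = config$n_boot,
                                      seed = derive_seed(config$seed, "boot", g)))
    run_stage("preferential_sampling",
              run_preferential_sampling(records_in, g, n_perm = config$n_perm,
                                        seed = derive_seed(config$seed, "perm", g),
                                        include_participant_slope = is_adult))
    run_stage("chance_corrected_beta", run_chance_corrected_beta(records_in, g))
    run_stage("sampling_accuracy_preregistered",
              run_sampling_accuracy(records_in, g, "preregistered"))
    run_stage("sampling_accuracy_posthoc",
              run_sampling_accuracy(records_in, g, "posthoc"))
    run_stage("sampling_interaction", run_sampling_interaction(records_in, g))
  }
  structure(list(
    reports = reports,
    exclusions = excl,
    errors = errors,
    fingerprint = list(package = "udsamp",
                       version = as.character(utils::packageVersion("udsamp")),
                       seed = config$seed, n_perm = config$n_perm,
                       n_boot = config$n_boot,
                       exclusion_threshold = config$exclusion_threshold,
                       simulated = !is.null(config$simulation)),
    complete = length(errors) == 0L
  ), class = "uds_bundle")
}

#' @export
print.uds_bundle <- function(x, ...) {
  cat(sprintf("<uds_bundle> %d group(s), complete = %s\n",
              length(x$reports), x$complete))
  if (length(x$errors)) {
    cat("failed stages:\n")
    for (nm in names(x$errors)) cat(sprintf("  %s: %s\n", nm, x$errors[[nm]]))
  }
  invisible(x)
}

# Flatten one report into CSV rows (term, estimate, se, statistic, p).
report_to_df <- function(rep, group, analysis) {
  if (is.null(rep)) {
    return(data.frame(analysis = analysis, group = group, kind = "error",
                      term = NA, estimate = NA, se = NA, method = NA,
                      statistic = NA, p_value = NA, note = "stage failed or no data",
                      stringsAsFactors = FALSE))
  }
  rows <- list()
  for (fn in names(rep$fits)) {
    f <- rep$fits[[fn]]
    rows[[length(rows) + 1L]] <- data.frame(
      analysis = analysis, group = group, kind = paste0("fit:", fn),
      term = names(f$estimates), estimate = as.numeric(f$estimates),
      se = as.numeric(f$standard_errors), method = NA_character_,
      statistic = NA_real_, p_value = NA_real_,
      note = if (f$converged) "" else "not converged",
      stringsAsFactors = FALSE)
  }
  for (tn in names(rep$tests)) {
    t <- rep$tests[[tn]]
    rows[[length(rows) + 1L]] <- data.frame(
      analysis = analysis, group = group, kind = paste0("test:", tn),
      term = tn, estimate = NA_real_, se = NA_real_, method = t$method,
      statistic = t$statistic, p_value = t$p_value, note = "",
      stringsAsFactors = FALSE)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    analysis = analysis, group = group, kind = "counts", term = "participants",
    estimate = rep$n_included, se = NA_real_, method = NA_character_,
    statistic = rep$n_removed, p_value = NA_real_,
    note = "estimate = n_included, statistic = n_removed",
    stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

#' Write a report bundle to disk
#'
#' Writes one machine-readable CSV per analysis per group
#' (`<group>_<analysis>.csv`, columns term/estimate/se/statistic/p), plus a
#' combined human-readable `summary.md` including the configuration
#' fingerprint, seed, exclusion log and any failed stages.
#'
#' @param bundle a `uds_bundle` from [run_full_pipeline()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "uds_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (g in names(bundle$reports)) {
    for (a in names(bundle$reports[[g]])) {
      p <- file.path(dir, sprintf("%s_%s.csv", gsub("[^A-Za-z0-9_-]", "_", g), a))
      utils::write.csv(report_to_df(bundle$reports[[g]][[a]], g, a), p,
                       row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  sm <- file.path(dir, "summary.md")
  con <- file(sm, "w", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  fp <- bundle$fingerprint
  w("# Analysis report")
  w("")
  w("- package: %s %s", fp$package, fp$version)
  w("- seed: %d | n_perm: %d | n_boot: %d | exclusion threshold: %d | simulated input: %s",
    fp$seed, fp$n_perm, fp$n_boot, fp$exclusion_threshold, fp$simulated)
  w("")
  w("## Exclusions (control score < %d of 9)", fp$exclusion_threshold)
  exc <- bundle$exclusions$scores
  w("- participants supplied: %d; excluded: %d", nrow(exc), sum(exc$excluded))
  if (any(exc$excluded)) {
    w("- excluded: %s (scores %s)",
      paste(exc$participant_id[exc$excluded], collapse = ", "),
      paste(exc$score[exc$excluded], collapse = ", "))
  }
  w("")
  for (g in names(bundle$reports)) {
    w("## Group: %s", g)
    for (a in names(bundle$reports[[g]])) {
      r <- bundle$reports[[g]][[a]]
      if (is.null(r)) {
        w("- %s: FAILED (%s)", a,
          bundle$errors[[paste(g, a, sep = "/")]] %||% "no data")
        next
      }
      line <- sprintf("- %s: n_included = %d, n_removed = %d", a,
                      r$n_included, r$n_removed)
      for (tn in names(r$tests)) {
        t <- r$tests[[tn]]
        line <- paste0(line, sprintf("; %s %s p = %.4g", tn, t$method, t$p_value))
      }
      w("%s", line)
      if (length(r$notes)) w("  - note: %s", paste(r$notes, collapse = "; "))
    }
    w("")
  }
  if (length(bundle$errors)) {
    w("## Failed stages")
    for (nm in names(bundle$errors)) w("- %s: %s", nm, bundle$errors[[nm]])
  } else {
    w("All stages completed.")
  }
  invisible(c(paths, sm))
}
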