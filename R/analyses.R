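#' Score knowledge-judgement control trials and flag exclusions
#'
#' Each participant judges 9 control items (5 familiar, 4 unfamiliar). The
#' control score counts correct judgements: familiar items judged known plus
#' unfamiliar items judged unknown, out of 9. Participants scoring below the
#' threshold (default: fewer than 5 of 9) are flagged for exclusion; a score
#' of exactly 5 is included.
#'
#' @param controls data.frame with `participant_id`, `item_class`
#'   (`"familiar"`/`"unfamiliar"`) and `judged_known` (0/1); exactly 9 rows
#'   (5 familiar + 4 unfamiliar) per participant.
#' @param threshold minimum score for inclusion (default 5).
#' @return a list: `scores` (data.frame `participant_id`, `score`,
#'   `excluded`) and `included` (character vector of retained participants).
#' @export
score_controls_and_exclude <- function(controls, threshold = 5L) {
  stopifnot(is.data.frame(controls))
  need <- c("participant_id", "item_class", "judged_known")
  if (!all(need %in% names(controls))) {
    stop("controls table needs columns participant_id, item_class, judged_known",
         call. = FALSE)
  }
  counts <- table(controls$participant_id, controls$item_class)
  bad <- rownames(counts)[counts[, "familiar"] != 5L | counts[, "unfamiliar"] != 4L]
  if (length(bad)) {
    stop(sprintf("participant(s) without 5 familiar + 4 unfamiliar control trials: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  correct <- ifelse(controls$item_class == "familiar",
                    controls$judged_known, 1L - controls$judged_known)
  score <- tapply(correct, controls$participant_id, sum)
  scores <- data.frame(participant_id = names(score),
                       score = as.integer(score),
                       excluded = as.integer(score) < threshold,
                       stringsAsFactors = FALSE, row.names = NULL)
  list(scores = scores,
       included = scores$participant_id[!scores$excluded])
}

#' Build the two-column sampling matrix
#'
#' One row per participant x object with the aggregated binomial response
#' pair: `times_sampled` (0--3) and `times_not_sampled = 3 - times_sampled`,
#' together with that object's knowledge judgement. The per-participant
#' `times_sampled` column must sum to the number of sampling choices (3).
#'
#' @param records participant-object records (see [simulate_experiment()]).
#' @param n_choices total sampling choices per participant, default 3.
#' @return data.frame `participant_id`, `object_id`, `times_sampled`,
#'   `times_not_sampled`, `knowledge_judgement`.
#' @export
build_sampling_matrix <- function(records, n_choices = 3L) {
  stopifnot(is.data.frame(records))
  sums <- tapply(records$times_sampled, records$participant_id, sum)
  bad <- names(sums)[sums != n_choices]
  if (length(bad)) {
    stop(sprintf("times_sampled does not sum to %d for participant(s): %s",
                 n_choices, paste(bad, collapse = ", ")), call. = FALSE)
  }
  data.frame(
    participant_id = records$participant_id,
    object_id = records$object_id,
    times_sampled = as.integer(records$times_sampled),
    times_not_sampled = as.integer(n_choices - records$times_sampled),
    knowledge_judgement = as.integer(records$knowledge_judgement),
    stringsAsFactors = FALSE
  )
}

# ---- analysis report container ---------------------------------------------

new_report <- function(analysis, group, fits = list(), tests = list(),
                       n_included, n_removed, notes = character(), ...) {
  structure(list(analysis = analysis, group = group, fits = fits,
                 tests = tests, n_included = n_included, n_removed = n_removed,
                 notes = notes, ...),
            class = "uds_report")
}

#' @export
print.uds_report <- function(x, ...) {
  cat(sprintf("<uds_report> %s [%s]: n_included = %d, n_removed = %d\n",
              x$analysis, x$group, x$n_included, x$n_removed))
  for (nm in names(x$tests)) {
    t <- x$tests[[nm]]
    if (inherits(t, "uds_test")) {
      cat(sprintf("  %s: %s statistic = %.3f, p = %.4g\n", nm, t$method,
                  t$statistic, t$p_value))
    }
  }
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

filter_group <- function(records, group) {
  if (!is.null(group)) records <- records[records$age_group == group, , drop = FALSE]
  if (nrow(records) == 0L) stop(sprintf("no data for group '%s'", group), call. = FALSE)
  records
}

n_participants_of <- function(records) length(unique(records$participant_id))

# Fit, and if a random-slope term comes back singular, refit without the
# slopes and record the decision -- mirroring the practice of dropping
# non-identifiable slope terms.
fit_drop_singular_slopes <- function(spec, table, nAGQ = 1L) {
  notes <- character()
  fit <- fit_logistic_mixed(spec, table, nAGQ = nAGQ)
  has_slopes <- any(lengths(spec$random_terms) > 0)
  if (fit$singular && has_slopes) {
    spec2 <- spec
    spec2$random_terms <- lapply(spec$random_terms, function(s) character())
    fit2 <- fit_logistic_mixed(spec2, table, nAGQ = nAGQ)
    notes <- "random slope(s) dropped: variance estimate on boundary (non-identifiable)"
    return(list(fit = fit2, spec = spec2, notes = notes, dropped = TRUE))
  }
  list(fit = fit, spec = spec, notes = notes, dropped = FALSE)
}

# ---- planned analyses -------------------------------------------------------

#' Overall test accuracy versus chance
#'
#' Intercept-only logistic mixed model for test accuracy with crossed random
#' intercepts of participant and object, followed by a Wald z-test of the
#' intercept against the chance level of guessing one object out of
#' `n_objects`, expressed in link space (`logit(1/6) = -1.609` for six
#' objects).
#'
#' @param records participant-object records, exclusions already applied.
#' @param group age-group label to analyse (or `NULL` for all rows).
#' @param n_objects number of response options per test trial, default 6.
#' @return a `uds_report` with the fit and the Wald test (`chance_wald`).
#' @export
run_overall_accuracy <- function(records, group = NULL, n_objects = 6L) {
  records <- filter_group(records, group)
  n_all <- n_participants_of(records)
  if (n_all < 2L) stop("need at least 2 participants", call. = FALSE)
  spec <- model_spec("test_correct",
                     random_terms = list(participant_id = character(),
                                         object_id = character()))
  fit <- fit_logistic_mixed(spec, records)
  notes <- character()
  tests <- list()
  if ("(Intercept)" %in% fit$non_estimable) {
    notes <- "intercept non-estimable (complete separation); no chance comparison"
  } else {
    tests$chance_wald <- wald_test(fit, "(Intercept)", logit(1 / n_objects))
  }
  new_report("overall_accuracy", group %||% "all", fits = list(accuracy = fit),
             tests = tests, n_included = n_all, n_removed = 0L, notes = notes,
             chance_link = logit(1 / n_objects))
}

#' Confidence-accuracy calibration
#'
#' Logistic mixed model of the binary confidence rating ("sure my answer was
#' correct") on test accuracy, with random intercepts and -- where
#' identifiable -- random slopes of accuracy within participant and object.
#' Significance of the accuracy effect is assessed by a likelihood-ratio test
#' against the model lacking the fixed effect. Also reports the fitted
#' population-level probability of a "sure" rating after correct and
#' incorrect answers, with parametric bootstrap intervals when `n_boot > 0`.
#'
#' @param records participant-object records, exclusions applied.
#' @param group age-group label.
#' @param include_random_slopes start from the full random-slope structure
#'   (`TRUE`, the child-group convention); `FALSE` fits intercepts-only
#'   within participant, as done for adults where the slope was not
#'   identifiable. Singular slope terms are dropped automatically either way.
#' @param n_boot bootstrap replicates for the fitted-probability intervals
#'   (0 = skip).
#' @param seed seed for the bootstrap (required when `n_boot > 0`).
#' @return a `uds_report` with the fit, LRT, and `fitted_probs`.
#' @export
run_confidence_accuracy <- function(records, group = NULL,
                                    include_random_slopes = TRUE,
                                    n_boot = 0, seed = NULL) {
  records <- filter_group(records, group)
  n_all <- n_participants_of(records)
  if (length(unique(records$confidence_rating)) < 2L) {
    return(new_report("confidence_accuracy", group %||% "all",
                      n_included = n_all, n_removed = 0L,
                      notes = "constant confidence rating: model non-estimable"))
  }
  rt <- if (include_random_slopes) {
    list(participant_id = "test_correct", object_id = "test_correct")
  } else {
    list(participant_id = character(), object_id = "test_correct")
  }
  spec <- model_spec("confidence_rating", "test_correct", rt)
  full <- fit_drop_singular_slopes(spec, records)
  if ("test_correct" %in% full$fit$non_estimable) {
    return(new_report("confidence_accuracy", group %||% "all",
                      fits = list(confidence = full$fit),
                      n_included = n_all, n_removed = 0L,
                      notes = c(full$notes,
                                "accuracy effect non-estimable (separation)")))
  }
  # lacking the fixed effect of accuracy but otherwise identical: the random
  # structure (including any surviving accuracy slopes) is kept as-is
  spec_red <- full$spec
  spec_red$fixed_terms <- character()
  red <- fit_logistic_mixed(spec_red, records)
  lrt <- likelihood_ratio_test(full$fit, red)

  b <- full$fit$estimates
  fitted_probs <- c(incorrect = inv_logit(b[["(Intercept)"]]),
                    correct = inv_logit(b[["(Intercept)"]] + b[["test_correct"]]))
  intervals <- NULL
  if (n_boot > 0) {
    if (is.null(seed)) stop("seed required when n_boot > 0", call. = FALSE)
    intervals <- parametric_bootstrap_ci(
      full$fit, n_boot = n_boot, seed = seed,
      fitted_newdata = data.frame(test_correct = c(0, 1)))
  }
  new_report("confidence_accuracy", group %||% "all",
             fits = list(confidence = full$fit, reduced = red),
             tests = list(lrt = lrt),
             n_included = n_all, n_removed = 0L, notes = full$notes,
             fitted_probs = fitted_probs, intervals = intervals)
}

# ---- permutation test -------------------------------------------------------

#' Within-participant permutation test for the sampling-matrix model
#'
#' The two-column model regresses the aggregated pair (times sampled, times
#' not sampled) on the knowledge judgement. Because a participant's six
#' response rows encode only three real decisions, the aggregated binomial
#' likelihood overstates the sample size and the naive Wald p-value is
#' anticonservative. This test instead permutes the response rows of the
#' two-column matrix across objects *within* each participant (judgements
#' stay in place), refits, and locates the observed statistic -- the absolute
#' knowledge-judgement estimate -- in the permutation distribution. The
#' observed data count as one of the `n_perm` permutations, so the smallest
#' attainable p is `1/n_perm`; ties count toward p ("at least as large").
#'
#' @param sampling_rows output of [build_sampling_matrix()].
#' @param n_perm total permutations including the observed data (default
#'   1000).
#' @param seed integer seed for the permutation stream.
#' @param include_participant_slope add a random slope of judgement within
#'   participant (the adult convention) on top of
#'   `(1|participant) + (1 + judgement|object)`.
#' @param nAGQ likelihood approximation for all fits in the permutation
#'   scheme (observed and permuted alike, so the statistic stays
#'   exchangeable); 0 is fast and is the default for simulation studies,
#'   1 the Laplace approximation.
#' @return a `uds_permutation`: `observed_statistic`,
#'   `permuted_statistics` (observed included), `p_value`, `n_perm`,
#'   `n_failed`, `seed`, and the observed `fit`.
#' @export
permutation_test_sampling <- function(sampling_rows, n_perm = 1000, seed,
                                      include_participant_slope = FALSE,
                                      nAGQ = 1L) {
  stopifnot(is.data.frame(sampling_rows))
  if (missing(seed)) stop("a seed is required for the permutation test", call. = FALSE)
  if (n_participants_of(sampling_rows) < 2L) {
    stop("need at least 2 participants", call. = FALSE)
  }
  if (stats::var(sampling_rows$knowledge_judgement) == 0) {
    stop("knowledge judgement is constant: predictor non-estimable", call. = FALSE)
  }
  rt <- list(participant_id = if (include_participant_slope) "knowledge_judgement" else character(),
             object_id = "knowledge_judgement")
  spec <- model_spec(c("times_sampled", "times_not_sampled"),
                     "knowledge_judgement", rt)
  obs_fit <- fit_logistic_mixed(spec, sampling_rows, nAGQ = nAGQ)
  obs_stat <- abs(obs_fit$estimates[["knowledge_judgement"]])

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(derive_seed(seed, "permutation"))

  idx_by_pid <- split(seq_len(nrow(sampling_rows)), sampling_rows$participant_id)
  resp <- as.matrix(sampling_rows[, c("times_sampled", "times_not_sampled")])
  stats_perm <- rep(NA_real_, n_perm - 1L)
  n_failed <- 0L
  for (b in seq_len(n_perm - 1L)) {
    perm_resp <- resp
    for (ix in idx_by_pid) perm_resp[ix, ] <- resp[sample(ix), , drop = FALSE]
    s <- try(perm_statistic(obs_fit$model, perm_resp), silent = TRUE)
    if (inherits(s, "try-error") || !is.finite(s)) n_failed <- n_failed + 1L
    else stats_perm[b] <- s
  }
  if (n_failed > 0.1 * n_perm) {
    stop(sprintf("permutation test: %d of %d refits failed (> 10%%)",
                 n_failed, n_perm), call. = FALSE)
  }
  all_stats <- c(obs_stat, stats_perm[!is.na(stats_perm)])
  p <- mean(all_stats >= obs_stat)
  structure(list(observed_statistic = obs_stat,
                 permuted_statistics = all_stats,
                 p_value = p, n_perm = n_perm, n_failed = n_failed,
                 seed = seed, fit = obs_fit),
            class = "uds_permutation")
}

perm_statistic <- function(model, perm_resp) {
  rf <- suppressMessages(suppressWarnings(lme4::refit(model, newresp = perm_resp)))
  abs(lme4::fixef(rf)[["knowledge_judgement"]])
}

#' @export
print.uds_permutation <- function(x, ...) {
  cat(sprintf("<uds_permutation> observed |estimate| = %.4f, p = %.4g (n_perm = %d, failed = %d)\n",
              x$observed_statistic, x$p_value, x$n_perm, x$n_failed))
  invisible(x)
}

#' Preferential sampling of judged-unknown objects
#'
#' Builds the two-column sampling matrix, fits
#' `(sampled, not sampled) ~ knowledge_judgement + (1|participant) +
#' (1 + judgement|object)` (plus a judgement slope within participant for the
#' adult convention), and reports the judgement estimate with the naive Wald
#' p-value and the within-participant permutation p-value side by side. The
#' permutation p is the one to trust; the Wald p is reported to document its
#' anticonservativeness for this response construction.
#'
#' The estimate's sign is interpreted against the predictor coding
#' (0 = "I don't know the label", 1 = "I know the label"): a *negative*
#' judgement estimate means judged-unknown objects were sampled more, i.e.
#' uncertainty-driven sampling. The permutation statistic is the absolute
#' estimate and is therefore coding-invariant.
#'
#' @inheritParams permutation_test_sampling
#' @param records participant-object records, exclusions applied.
#' @param group age-group label.
#' @return a `uds_report` with the fit, `wald` and `permutation` tests, and
#'   a `direction` note in probability terms.
#' @export
run_preferential_sampling <- function(records, group = NULL, n_perm = 1000,
                                      seed, include_participant_slope = (identical(group, "adult")),
                                      nAGQ = 1L) {
  records <- filter_group(records, group)
  n_all <- n_participants_of(records)
  rows <- build_sampling_matrix(records)
  if (stats::var(rows$knowledge_judgement) == 0) {
    return(new_report("preferential_sampling", group %||% "all",
                      n_included = n_all, n_removed = 0L,
                      notes = "knowledge judgement constant: predictor non-estimable"))
  }
  perm <- permutation_test_sampling(rows, n_perm = n_perm, seed = seed,
                                    include_participant_slope = include_participant_slope,
                                    nAGQ = nAGQ)
  fit <- perm$fit
  wald <- wald_test(fit, "knowledge_judgement", 0)
  est <- fit$estimates[["knowledge_judgement"]]
  direction <- if (est < 0) {
    "judged-unknown objects sampled more than judged-known (uncertainty-driven)"
  } else {
    "judged-known objects sampled more than judged-unknown"
  }
  new_report("preferential_sampling", group %||% "all",
             fits = list(sampling = fit),
             tests = list(wald = wald, permutation = structure(
               list(statistic = perm$observed_statistic, df = NA_integer_,
                    p_value = perm$p_value, method = "permutation"),
               class = "uds_test")),
             n_included = n_all, n_removed = 0L,
             notes = c(sprintf("direction: %s", direction)),
             permutation = perm)
}

# ---- chance-corrected sampling statistic ------------------------------------

#' Chance-corrected proportion of unknown objects sampled
#'
#' Per participant, compares the proportion of judged-unknown objects they
#' sampled with the proportion available, and maps the difference into
#' (0, 1):
#' \deqn{r = \frac{u_s/\min(u_a, 3) - u_a/6}{2} + 0.5}
#' where \eqn{u_s} is the number of *unique* judged-unknown objects sampled
#' and \eqn{u_a} the number of unique judged-unknown objects available. The
#' first denominator is capped at 3 because only three sampling choices
#' exist; the availability denominator (6 objects) is not capped. The
#' statistic is 0.5 exactly when sampling is at chance, above 0.5 for
#' uncertainty-driven sampling, strictly inside (0, 1) always.
#'
#' Participants who judged all or none of the objects unknown carry no
#' information (they necessarily sampled all-known or all-unknown) and raise
#' a classed error (`uds_exclusion`); callers exclude them upstream.
#'
#' @param judgements binary vector, one knowledge judgement per object
#'   (1 = known, 0 = unknown).
#' @param sampled indices (or logical mask) of the *distinct* objects
#'   sampled.
#' @param n_choices sampling choices available (cap for the sampled-
#'   proportion denominator), default 3.
#' @return the chance-corrected response, a number strictly in (0, 1).
#' @export
#' @examples
#' chance_corrected_response(c(0, 0, 1, 1, 1, 1), sampled = c(1, 2, 3))
chance_corrected_response <- function(judgements, sampled, n_choices = 3L) {
  n <- length(judgements)
  stopifnot(all(judgements %in% 0:1))
  if (is.logical(sampled)) sampled <- which(sampled)
  sampled <- unique(as.integer(sampled))
  if (any(sampled < 1L | sampled > n)) stop("sampled indices out of range", call. = FALSE)
  u_avail <- sum(judgements == 0)
  if (u_avail == 0L || u_avail == n) {
    stop(structure(class = c("uds_exclusion", "error", "condition"),
                   list(message = sprintf(
                     "participant judged %s objects unknown: chance-corrected response undefined, exclude upstream",
                     if (u_avail == 0L) "no" else "all"), call = NULL)))
  }
  u_sampled <- sum(judgements[sampled] == 0)
  (u_sampled / min(u_avail, n_choices) - u_avail / n) / 2 + 0.5
}

# Per-participant chance-corrected responses from long records. Returns a
# data.frame with one row per participant and an `excluded` flag for the
# all-known / all-unknown cases. Uses each object's row as one distinct
# object (sampling without replacement makes times_sampled > 0 the sampled
# set; repeated sampling still counts the object once, as required).
chance_corrected_by_participant <- function(records, n_choices = 3L) {
  by_pid <- split(records, records$participant_id)
  out <- lapply(names(by_pid), function(pid) {
    r <- by_pid[[pid]]
    val <- tryCatch(
      chance_corrected_response(r$knowledge_judgement,
                                sampled = r$times_sampled > 0,
                                n_choices = n_choices),
      uds_exclusion = function(e) NA_real_)
    data.frame(participant_id = pid, response = val,
               excluded = is.na(val), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Chance-corrected sampling analysis (beta regression)
#'
#' Computes the chance-corrected response per participant (see
#' [chance_corrected_response()]), removes participants who judged all or no
#' objects unknown, fits an intercept-only beta regression with logit link,
#' and Wald-tests the intercept against 0 in link space (the chance
#' reference, since `logit(0.5) = 0`).
#'
#' @param records participant-object records, exclusions applied.
#' @param group age-group label.
#' @return a `uds_report`; `n_removed` counts the all/none-unknown
#'   participants.
#' @export
run_chance_corrected_beta <- function(records, group = NULL) {
  records <- filter_group(records, group)
  n_all <- n_participants_of(records)
  cc <- chance_corrected_by_participant(records)
  dat <- cc[!cc$excluded, , drop = FALSE]
  if (nrow(dat) < 5L) {
    stop(sprintf("only %d participants with an informative judgement mix (need >= 5)",
                 nrow(dat)), call. = FALSE)
  }
  fit <- fit_beta_glm(dat, "response")
  wald <- wald_test(fit, "(Intercept)", 0)
  new_report("chance_corrected_beta", group %||% "all",
             fits = list(beta = fit), tests = list(chance_wald = wald),
             n_included = nrow(dat), n_removed = n_all - nrow(dat),
             responses = cc)
}

# ---- sampling benefit and interaction ---------------------------------------

#' Effect of uncertainty-driven sampling on test accuracy
#'
#' Regresses test accuracy on the (z-standardized) proportion of
#' judged-unknown objects sampled, with random intercepts of participant and
#' object and a random slope of the predictor within object.
#'
#' Two predictor constructions are supported:
#' \describe{
#'   \item{`"preregistered"`}{unique judged-unknown objects sampled out of
#'     the three possible choices (x/3); no extra exclusions.}
#'   \item{`"posthoc"`}{unique judged-unknown objects sampled out of the
#'     unique judged-unknown objects *available*; participants with zero
#'     unknown objects are removed (the ratio is undefined for them).}
#' }
#' The predictor is z-standardized over the participants remaining after all
#' exclusions, so it has mean 0 and sd 1 in the fitted table.
#'
#' @param records participant-object records, exclusions applied.
#' @param group age-group label.
#' @param mode `"preregistered"` or `"posthoc"`.
#' @return a `uds_report` with the fit and the slope's Wald test.
#' @export
run_sampling_accuracy <- function(records, group = NULL,
                                  mode = c("preregistered", "posthoc")) {
  mode <- match.arg(mode)
  records <- filter_group(records, group)
  n_all <- n_participants_of(records)
  by_pid <- split(records, records$participant_id)
  u_sampled <- vapply(by_pid, function(r) sum(r$knowledge_judgement == 0 & r$times_sampled > 0), 0)
  u_avail <- vapply(by_pid, function(r) sum(r$knowledge_judgement == 0), 0)

  if (mode == "preregistered") {
    prop <- u_sampled / 3
    keep <- names(by_pid)
  } else {
    keep <- names(by_pid)[u_avail > 0]
    prop <- (u_sampled / u_avail)[u_avail > 0]
  }
  n_removed <- n_all - length(keep)
  dat <- records[records$participant_id %in% keep, , drop = FALSE]
  if (length(unique(prop)) < 2L) {
    return(new_report(paste0("sampling_accuracy_", mode), group %||% "all",
                      n_included = length(keep), n_removed = n_removed,
                      notes = "constant predictor after exclusions: non-estimable"))
  }
  prop_z <- stats::setNames(z_standardize(prop), keep)
  dat$prop_unknown_sampled_z <- prop_z[dat$participant_id]

  spec <- model_spec("test_correct", "prop_unknown_sampled_z",
                     list(participant_id = character(),
                          object_id = "prop_unknown_sampled_z"))
  res <- fit_drop_singular_slopes(spec, dat)
  tests <- list()
  if (!"prop_unknown_sampled_z" %in% res$fit$non_estimable) {
    tests$slope_wald <- wald_test(res$fit, "prop_unknown_sampled_z", 0)
  }
  new_report(paste0("sampling_accuracy_", mode), group %||% "all",
             fits = list(accuracy = res$fit), tests = tests,
             n_included = length(keep), n_removed = n_removed,
             notes = res$notes)
}

#' Does sampling help, and does it help more for unknown objects?
#'
#' Logistic mixed model of test accuracy on the number of times each object
#' was sampled (0--3), the object's knowledge judgement (0 = unknown,
#' 1 = known) and their interaction, with random intercepts of participant
#' and object. Three nested fits are compared: the full model
#' (sampling x judgement), a null model with no sampling terms (judgement
#' only), and a reduced model without the interaction. Reported: the
#' interaction's Wald p, the full-vs-null LRT p (overall impact of
#' sampling), and the reduced model's main sampling effect. Fitted
#' population-level probabilities are emitted for the sampling (0--3) by
#' judgement grid; cells with no supporting data are flagged.
#'
#' @param records participant-object records, exclusions applied.
#' @param group age-group label.
#' @return a `uds_report` with fits `full`, `null`, `reduced`, tests
#'   `interaction_wald`, `sampling_lrt`, `sampling_wald_reduced`, and
#'   `fitted_cells`.
#' @export
run_sampling_interaction <- function(records, group = NULL) {
  records <- filter_group(records, group)
  n_all <- n_participants_of(records)
  notes <- character()
  if (stats::var(records$times_sampled) == 0) {
    return(new_report("sampling_interaction", group %||% "all",
                      n_included = n_all, n_removed = 0L,
                      notes = "times_sampled constant: sampling terms non-estimable"))
  }
  if (stats::var(records$knowledge_judgement) == 0) {
    return(new_report("sampling_interaction", group %||% "all",
                      n_included = n_all, n_removed = 0L,
                      notes = "knowledge judgement constant: model non-estimable"))
  }
  dat <- records
  dat$sampling_x_judgement <- dat$times_sampled * dat$knowledge_judgement
  re <- list(participant_id = character(), object_id = character())
  full <- fit_logistic_mixed(
    model_spec("test_correct",
               c("times_sampled", "knowledge_judgement", "sampling_x_judgement"), re), dat)
  nullm <- fit_logistic_mixed(
    model_spec("test_correct", "knowledge_judgement", re), dat)
  reduced <- fit_logistic_mixed(
    model_spec("test_correct", c("times_sampled", "knowledge_judgement"), re), dat)

  tests <- list()
  if (!"sampling_x_judgement" %in% full$non_estimable) {
    tests$interaction_wald <- wald_test(full, "sampling_x_judgement", 0)
  } else {
    notes <- c(notes, "interaction non-estimable")
  }
  tests$sampling_lrt <- likelihood_ratio_test(full, nullm)
  if (!"times_sampled" %in% reduced$non_estimable) {
    tests$sampling_wald_reduced <- wald_test(reduced, "times_sampled", 0)
  }

  grid <- expand.grid(times_sampled = 0:3, knowledge_judgement = 0:1)
  grid$sampling_x_judgement <- grid$times_sampled * grid$knowledge_judgement
  b <- full$estimates
  grid$fitted_prob <- inv_logit(b[["(Intercept)"]] +
                                  b[["times_sampled"]] * grid$times_sampled +
                                  b[["knowledge_judgement"]] * grid$knowledge_judgement +
                                  b[["sampling_x_judgement"]] * grid$sampling_x_judgement)
  obs_cells <- unique(records[, c("times_sampled", "knowledge_judgement")])
  grid$observed <- interaction(grid$times_sampled, grid$knowledge_judgement) %in%
    interaction(obs_cells$times_sampled, obs_cells$knowledge_judgement)
  if (any(!grid$observed)) {
    notes <- c(notes, "some sampling-by-judgement cells have no data; their fitted values are extrapolations")
  }
  new_report("sampling_interaction", group %||% "all",
             fits = list(full = full, null = nullm, reduced = reduced),
             tests = tests, n_included = n_all, n_removed = 0L,
             notes = notes, fitted_cells = grid)
}
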