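#' Replicated simulate-and-test study for the sampling permutation test
#'
#' Repeatedly simulates a single-group experiment with a given
#' uncertainty-driven sampling weight `w`, runs the two-column
#' sampling-matrix model on each replicate, and records the knowledge-
#' judgement estimate together with the naive Wald p-value and the
#' within-participant permutation p-value. With `w = 0` this estimates the
#' type-I error rate of both procedures (the aggregated two-column response
#' pretends each participant made 18 decisions instead of 3, so the naive
#' Wald test is expected to be anticonservative while the permutation test
#' stays nominal); with `w > 0` it estimates power and effect recovery.
#'
#' @param n_reps number of simulated replicates.
#' @param n_participants participants per replicate (single group).
#' @param w generating `sampling_preference_w` (log-odds preference for
#'   judged-unknown objects).
#' @param n_perm permutations per replicate (observed data included).
#' @param seed master seed; replicate r uses substream (seed, "rep", r).
#' @param p_learn,judge_known_given_learned,judge_known_given_unlearned
#'   passed to [simulation_config()] (defaults: adult-like learning).
#' @param nAGQ approximation used for every fit inside the study (default 0,
#'   the fast penalized-likelihood step -- the same for observed and
#'   permuted fits, preserving exchangeability).
#' @return data.frame with one row per replicate: `estimate`, `wald_p`,
#'   `perm_p`, `n_failed_perms`.
#' @export
sampling_permutation_study <- function(n_reps, n_participants = 50, w = 0,
                                       n_perm = 100, seed,
                                       p_learn = 0.81,
                                       judge_known_given_learned = 0.85,
                                       judge_known_given_unlearned = 0.30,
                                       nAGQ = 0L) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- simulation_config(
      n_participants = c(grp = n_participants),
      p_learn = p_learn,
      judge_known_given_learned = judge_known_given_learned,
      judge_known_given_unlearned = judge_known_given_unlearned,
      sampling_preference_w = w,
      seed = derive_seed(seed, "rep", r))
    dat <- simulate_experiment(cfg)
    rows <- build_sampling_matrix(dat$records)
    res <- try(permutation_test_sampling(rows, n_perm = n_perm,
                                         seed = derive_seed(seed, "perm", r),
                                         nAGQ = nAGQ), silent = TRUE)
    if (inherits(res, "try-error")) {
      out[[r]] <- data.frame(estimate = NA_real_, wald_p = NA_real_,
                             perm_p = NA_real_, n_failed_perms = NA_integer_)
      next
    }
    wald <- wald_test(res$fit, "knowledge_judgement", 0)
    out[[r]] <- data.frame(estimate = res$fit$estimates[["knowledge_judgement"]],
                           wald_p = wald$p_value, perm_p = res$p_value,
                           n_failed_perms = res$n_failed)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
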