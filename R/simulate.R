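#' Configuration for the experiment simulator
#'
#' Describes one simulated run of the word-learning / knowledge-judgement /
#' sampling / test design: each participant is trained on `n_objects` novel
#' object--label associations, gives a binary knowledge judgement per object,
#' makes exactly `n_sampling_choices` sampling choices over the objects (to
#' hear labels again), answers one test trial per object, rates confidence in
#' each answer, and additionally judges 9 control items (5 familiar, 4
#' unfamiliar).
#'
#' Every behavioural parameter may be a single value (applied to all groups)
#' or a vector named by age group. Group presets for `p_learn`
#' (0.31 / 0.44 / 0.81 for "5yo" / "6-9yo" / "adult") mirror typical
#' published group accuracies in this paradigm and are illustrative, not
#' fitted.
#'
#' @param n_participants named integer vector: participants per age group,
#'   e.g. `c("5yo" = 58, "6-9yo" = 64, adult = 50)`.
#' @param n_objects objects (and test trials) per participant. Default 6.
#' @param n_sampling_choices sampling choices per participant. Default 3.
#' @param p_learn probability that an object's label is learned (before
#'   random effects).
#' @param judge_known_given_learned,judge_known_given_unlearned probability
#'   of judging an object "known" given its latent learned state. A positive
#'   `judge_known_given_unlearned` encodes overconfidence.
#' @param sampling_preference_w log-odds weight favouring judged-unknown
#'   objects in the sampling phase; 0 means no preference (each object
#'   equally likely), positive values mean uncertainty-driven sampling.
#' @param p_correct_learned,p_correct_unlearned_base test accuracy for
#'   learned / unlearned objects before any sampling boost (probability
#'   scale; converted internally to log-odds). The unlearned base defaults
#'   to guessing, 1/6.
#' @param sampling_boost additive log-odds gain in test accuracy per time
#'   the object was sampled.
#' @param boost_unlearned_only if `TRUE` the sampling boost applies only to
#'   unlearned objects (learned ones are assumed at their ceiling).
#' @param p_sure_given_correct,p_sure_given_incorrect probability of rating
#'   "I am sure my answer was correct" given the answer's correctness.
#' @param sd_participant,sd_object standard deviations of logit-normal random
#'   intercepts shared by the learning and test-accuracy stages; 0 gives
#'   i.i.d. rows.
#' @param control_lapse probability of an erroneous control judgement
#'   (judging a familiar item unknown or an unfamiliar item known).
#' @param allow_repeat_sampling if `TRUE` the three sampling choices are
#'   drawn with replacement (the same object may be heard several times);
#'   default `FALSE`, matching the near-universal behaviour of choosing
#'   distinct objects.
#' @param seed integer RNG seed. Mandatory: identical seed and configuration
#'   give bit-identical output tables. Each participant draws from an own
#'   substream derived from this seed, so adding participants never perturbs
#'   existing ones.
#' @return an object of class `uds_config` (a validated list).
#' @seealso [simulate_experiment()], [group_presets()]
#' @export
simulation_config <- function(n_participants = c("5yo" = 58, "6-9yo" = 64, adult = 50),
                              n_objects = 6L,
                              n_sampling_choices = 3L,
                              p_learn = c("5yo" = 0.31, "6-9yo" = 0.44, adult = 0.81),
                              judge_known_given_learned = 0.85,
                              judge_known_given_unlearned = 0.30,
                              sampling_preference_w = c("5yo" = 0, "6-9yo" = 0.36, adult = 0.61),
                              p_correct_learned = 0.90,
                              p_correct_unlearned_base = 1 / 6,
                              sampling_boost = 0.6,
                              boost_unlearned_only = FALSE,
                              p_sure_given_correct = 0.88,
                              p_sure_given_incorrect = 0.55,
                              sd_participant = 1,
                              sd_object = 0.5,
                              control_lapse = 0.15,
                              allow_repeat_sampling = FALSE,
                              seed = NULL) {
  if (is.null(names(n_participants)) || any(!nzchar(names(n_participants)))) {
    stop("n_participants must be a named vector (one count per age group)",
         call. = FALSE)
  }
  groups <- names(n_participants)
  # the preset-named defaults only apply to the preset groups; unnamed custom
  # groups fall back to neutral values (p_learn 0.5, no sampling preference)
  if (missing(p_learn)) {
    p_learn <- vapply(groups, function(g) {
      switch(g, "5yo" = 0.31, "6-9yo" = 0.44, adult = 0.81, 0.5)
    }, 0)
  }
  if (missing(sampling_preference_w)) {
    sampling_preference_w <- vapply(groups, function(g) {
      switch(g, "5yo" = 0, "6-9yo" = 0.36, adult = 0.61, 0)
    }, 0)
  }

  chk_count <- function(x, nm, min = 1) {
    if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x < min || x != round(x)) {
      stop(sprintf("invalid config field '%s': must be an integer >= %d", nm, min),
           call. = FALSE)
    }
    as.integer(x)
  }
  chk_prob <- function(x, nm) {
    if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
      stop(sprintf("invalid config field '%s': probabilities must lie in [0, 1]", nm),
           call. = FALSE)
    }
    resolve_by_group(x, groups, nm)
  }
  chk_real <- function(x, nm, min = -Inf) {
    if (!is.numeric(x) || any(!is.finite(x)) || any(x < min)) {
      stop(sprintf("invalid config field '%s'", nm), call. = FALSE)
    }
    resolve_by_group(x, groups, nm)
  }

  n_objects <- chk_count(n_objects, "n_objects")
  n_sampling_choices <- chk_count(n_sampling_choices, "n_sampling_choices")
  if (n_sampling_choices > n_objects) {
    stop("invalid config field 'n_sampling_choices': must not exceed n_objects",
         call. = FALSE)
  }
  if (any(n_participants < 1) || any(n_participants != round(n_participants))) {
    stop("invalid config field 'n_participants': counts must be positive integers",
         call. = FALSE)
  }
  if (is.null(seed)) stop("invalid config field 'seed': a seed is required", call. = FALSE)
  seed <- chk_count(seed, "seed", min = 0)

  cfg <- list(
    n_participants = stats::setNames(as.integer(n_participants), groups),
    n_objects = n_objects,
    n_sampling_choices = n_sampling_choices,
    p_learn = chk_prob(p_learn, "p_learn"),
    judge_known_given_learned = chk_prob(judge_known_given_learned, "judge_known_given_learned"),
    judge_known_given_unlearned = chk_prob(judge_known_given_unlearned, "judge_known_given_unlearned"),
    sampling_preference_w = chk_real(sampling_preference_w, "sampling_preference_w"),
    p_correct_learned = chk_prob(p_correct_learned, "p_correct_learned"),
    p_correct_unlearned_base = chk_prob(p_correct_unlearned_base, "p_correct_unlearned_base"),
    sampling_boost = chk_real(sampling_boost, "sampling_boost"),
    boost_unlearned_only = isTRUE(boost_unlearned_only),
    p_sure_given_correct = chk_prob(p_sure_given_correct, "p_sure_given_correct"),
    p_sure_given_incorrect = chk_prob(p_sure_given_incorrect, "p_sure_given_incorrect"),
    sd_participant = chk_real(sd_participant, "sd_participant", min = 0),
    sd_object = chk_real(sd_object, "sd_object", min = 0),
    control_lapse = chk_prob(control_lapse, "control_lapse"),
    allow_repeat_sampling = isTRUE(allow_repeat_sampling),
    seed = seed
  )
  class(cfg) <- "uds_config"
  cfg
}

# Recycle a scalar over groups or check a group-named vector.
resolve_by_group <- function(x, groups, nm) {
  if (length(x) == 1L && is.null(names(x))) {
    return(stats::setNames(rep(as.numeric(x), length(groups)), groups))
  }
  if (is.null(names(x)) || !all(groups %in% names(x))) {
    stop(sprintf("invalid config field '%s': supply one value or a vector named by age group", nm),
         call. = FALSE)
  }
  stats::setNames(as.numeric(x[groups]), groups)
}

#' Illustrative per-group parameter presets
#'
#' Returns the default group presets ("5yo", "6-9yo", "adult") used by
#' [simulation_config()]: learning probabilities of roughly 0.31 / 0.44 /
#' 0.81 and uncertainty-driven sampling weights of 0 / 0.36 / 0.61. These
#' echo typical published group summaries in the paradigm (younger children
#' learn less and sample at random; older children and adults preferentially
#' sample judged-unknown objects) and are illustrative, not fitted.
#'
#' @return a data.frame with columns `group`, `n`, `p_learn`,
#'   `sampling_preference_w`.
#' @export
group_presets <- function() {
  data.frame(
    group = c("5yo", "6-9yo", "adult"),
    n = c(58L, 64L, 50L),
    p_learn = c(0.31, 0.44, 0.81),
    sampling_preference_w = c(0, 0.36, 0.61),
    stringsAsFactors = FALSE
  )
}

#' Weighted choice without replacement (Plackett--Luce scheme)
#'
#' Draws `k` distinct indices by sequential selection: at each step an item is
#' picked with probability proportional to its weight among the items still
#' remaining. Used by the simulator's sampling phase, where judged-unknown
#' objects get weight `exp(w)` and judged-known objects weight 1.
#'
#' @param weights positive finite weights, one per item.
#' @param k number of distinct items to draw, `k <= length(weights)`.
#' @return integer vector of `k` distinct indices into `weights`.
#' @export
weighted_choice_without_replacement <- function(weights, k) {
  if (!is.numeric(weights) || any(!is.finite(weights)) || any(weights <= 0)) {
    stop("weights must be positive finite numbers", call. = FALSE)
  }
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > length(weights)) {
    stop("k must be an integer between 1 and length(weights)", call. = FALSE)
  }
  remaining <- seq_along(weights)
  picked <- integer(k)
  for (i in seq_len(k)) {
    w <- weights[remaining]
    j <- remaining[sample.int(length(remaining), 1L, prob = w)]
    picked[i] <- j
    remaining <- remaining[remaining != j]
  }
  picked
}

#' Simulate one full experiment
#'
#' Generates the two long-format tables every downstream analysis consumes.
#' The generative process, per participant:
#' \enumerate{
#'   \item draw participant and object random intercepts
#'     `u_p ~ N(0, sd_participant^2)`, `u_o ~ N(0, sd_object^2)` (objects are
#'     drawn from a pool of 15 per group, so object effects are crossed with
#'     participants);
#'   \item `learned ~ Bernoulli(inv_logit(logit(p_learn) + u_p + u_o))`;
#'   \item `knowledge_judgement ~ Bernoulli(judge_known_given_learned)` for
#'     learned objects, `Bernoulli(judge_known_given_unlearned)` otherwise;
#'   \item sampling: `n_sampling_choices` weighted choices over the objects,
#'     without replacement by default, with per-object weight
#'     `exp(sampling_preference_w * (1 - knowledge_judgement))`;
#'   \item `test_correct ~ Bernoulli(inv_logit(base + sampling_boost *
#'     times_sampled + u_p + u_o))` with `base = logit(p_correct_learned)` or
#'     `logit(p_correct_unlearned_base)` by learned state;
#'   \item `confidence_rating ~ Bernoulli(p_sure_given_correct)` or
#'     `Bernoulli(p_sure_given_incorrect)` by correctness;
#'   \item 9 control judgements (5 familiar + 4 unfamiliar), each correct
#'     with probability `1 - control_lapse`.
#' }
#'
#' @param config a [simulation_config()] object.
#' @return a list of class `uds_data` with elements `records` (one row per
#'   participant x object: `participant_id`, `age_group`, `object_id`,
#'   `learned`, `knowledge_judgement`, `times_sampled`, `test_correct`,
#'   `confidence_rating`) and `controls` (one row per control trial:
#'   `participant_id`, `item_id`, `item_class`, `judged_known`).
#' @export
simulate_experiment <- function(config) {
  if (!inherits(config, "uds_config")) {
    stop("config must be created by simulation_config()", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)

  n_pool <- max(15L, config$n_objects)  # object pool size per group (crossed factor)
  rec_list <- list()
  ctl_list <- list()
  for (g in names(config$n_participants)) {
    # object random intercepts for this group's pool, own substream
    set.seed(derive_seed(config$seed, "objects", g))
    u_obj <- stats::rnorm(n_pool, 0, config$sd_object[g])
    for (i in seq_len(config$n_participants[[g]])) {
      set.seed(derive_seed(config$seed, "participant", g, i))
      pid <- sprintf("%s_p%03d", g, i)
      sim <- simulate_participant(pid, g, i, u_obj, config)
      rec_list[[pid]] <- sim$records
      ctl_list[[pid]] <- sim$controls
    }
  }
  out <- list(
    records = do.call(rbind, c(rec_list, list(make.row.names = FALSE))),
    controls = do.call(rbind, c(ctl_list, list(make.row.names = FALSE)))
  )
  class(out) <- "uds_data"
  out
}

simulate_participant <- function(pid, g, i, u_obj, cfg) {
  k <- cfg$n_objects
  objs <- sample.int(length(u_obj), k)        # which pool objects this participant saw
  u_p <- stats::rnorm(1, 0, cfg$sd_participant[g])
  u_o <- u_obj[objs]

  learned <- stats::rbinom(k, 1, inv_logit(logit_safe(cfg$p_learn[g]) + u_p + u_o))
  p_judge <- ifelse(learned == 1, cfg$judge_known_given_learned[g],
                    cfg$judge_known_given_unlearned[g])
  judgement <- stats::rbinom(k, 1, p_judge)

  w <- exp(cfg$sampling_preference_w[g] * (1 - judgement))
  if (cfg$allow_repeat_sampling) {
    picks <- sample.int(k, cfg$n_sampling_choices, replace = TRUE, prob = w)
  } else {
    picks <- weighted_choice_without_replacement(w, cfg$n_sampling_choices)
  }
  times_sampled <- tabulate(picks, nbins = k)

  base <- ifelse(learned == 1, logit_safe(cfg$p_correct_learned[g]),
                 logit_safe(cfg$p_correct_unlearned_base[g]))
  boost <- cfg$sampling_boost[g] * times_sampled
  if (cfg$boost_unlearned_only) boost <- boost * (1 - learned)
  test_correct <- stats::rbinom(k, 1, inv_logit(base + boost + u_p + u_o))

  p_sure <- ifelse(test_correct == 1, cfg$p_sure_given_correct[g],
                   cfg$p_sure_given_incorrect[g])
  confidence <- stats::rbinom(k, 1, p_sure)

  records <- data.frame(
    participant_id = pid,
    age_group = g,
    object_id = sprintf("obj%02d", objs),
    learned = learned,
    knowledge_judgement = judgement,
    times_sampled = times_sampled,
    test_correct = test_correct,
    confidence_rating = confidence,
    stringsAsFactors = FALSE
  )

  item_class <- c(rep("familiar", 5L), rep("unfamiliar", 4L))
  correct_resp <- ifelse(item_class == "familiar", 1L, 0L)
  lapse <- stats::rbinom(9L, 1, cfg$control_lapse[g])
  controls <- data.frame(
    participant_id = pid,
    item_id = c(sprintf("fam%d", 1:5), sprintf("unfam%d", 1:4)),
    item_class = item_class,
    judged_known = ifelse(lapse == 1, 1L - correct_resp, correct_resp),
    stringsAsFactors = FALSE
  )
  list(records = records, controls = controls)
}

# logit that tolerates 0/1 by mapping to +/-Inf (degenerate configs are legal
# in the simulator even though logit() itself rejects the boundary).
logit_safe <- function(p) {
  ifelse(p <= 0, -Inf, ifelse(p >= 1, Inf, log(p / (1 - p))))
}

#' Write simulated tables to CSV
#'
#' Writes `records.csv` and `controls.csv` (UTF-8, comma-separated, header
#' row) into `dir`, the exact schema [read_trial_table()] and
#' [read_control_table()] expect.
#'
#' @param data a `uds_data` object from [simulate_experiment()].
#' @param dir output directory (created if missing).
#' @return invisibly, the two file paths.
#' @export
write_experiment_csv <- function(data, dir) {
  stopifnot(inherits(data, "uds_data"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(records = file.path(dir, "records.csv"),
             controls = file.path(dir, "controls.csv"))
  utils::write.csv(data$records, paths[["records"]], row.names = FALSE, quote = FALSE)
  utils::write.csv(data$controls, paths[["controls"]], row.names = FALSE, quote = FALSE)
  invisible(paths)
}
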