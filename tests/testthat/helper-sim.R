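# Shared fixture builders. Everything is generated in code at test time.

# Small single-group simulated experiment.
sim_group <- function(n = 20, group = "adult", w = 0, seed = 1, ...) {
  cfg <- simulation_config(n_participants = stats::setNames(n, group),
                           sampling_preference_w = w, seed = seed, ...)
  simulate_experiment(cfg)
}

# Hand-built records for two participants with known sampling patterns.
tiny_records <- function() {
  data.frame(
    participant_id = rep(c("p1", "p2"), each = 6),
    age_group = "kids",
    object_id = rep(sprintf("o%d", 1:6), 2),
    learned = 0L,
    knowledge_judgement = c(0, 0, 1, 1, 1, 1,  1, 0, 1, 0, 1, 0),
    times_sampled = c(1, 1, 1, 0, 0, 0,  3, 0, 0, 0, 0, 0),
    test_correct = c(1, 0, 1, 0, 1, 0,  0, 1, 0, 1, 0, 1),
    confidence_rating = c(1, 1, 0, 0, 1, 0,  1, 0, 1, 0, 1, 0),
    stringsAsFactors = FALSE
  )
}

# Control table where participant scores are chosen exactly.
controls_with_scores <- function(scores) {
  out <- lapply(names(scores), function(pid) {
    s <- scores[[pid]]
    correct <- c(rep(1L, s), rep(0L, 9L - s))  # first s of the 9 judged right
    item_class <- c(rep("familiar", 5), rep("unfamiliar", 4))
    right <- ifelse(item_class == "familiar", 1L, 0L)
    data.frame(participant_id = pid,
               item_id = c(sprintf("f%d", 1:5), sprintf("u%d", 1:4)),
               item_class = item_class,
               judged_known = ifelse(correct == 1L, right, 1L - right),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
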