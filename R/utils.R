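#' Log-odds (logit) transform
#'
#' Maps a probability to the natural-log odds scale ("link space"). All fixed
#' effects and chance references in this package are expressed on this scale;
#' e.g. the chance level of picking the right object out of six is
#' `logit(1/6) = -1.609` (3 d.p.) and `logit(0.5) = 0`.
#'
#' @param p probability strictly inside (0, 1).
#' @return log-odds, `log(p / (1 - p))`.
#' @seealso [inv_logit()]
#' @export
#' @examples
#' logit(1/6)
#' inv_logit(logit(0.3))
logit <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("logit() is defined for probabilities strictly inside (0, 1)", call. = FALSE)
  }
  log(p / (1 - p))
}

#' Inverse logit
#'
#' @param x real number (any finite value, or +/-Inf which map to 1 and 0).
#' @return probability in (0, 1).
#' @rdname logit
#' @export
inv_logit <- function(x) {
  stats::plogis(x)
}

#' z-standardize a numeric vector
#'
#' Centres to sample mean 0 and scales to sample standard deviation 1.
#' Used for the proportion-of-unknown-objects-sampled predictor, which is
#' standardized over the participants actually entering the model (i.e. after
#' all exclusions).
#'
#' @param x numeric vector with at least two distinct finite values.
#' @return numeric vector of the same length with mean 0 and sd 1.
#' @export
z_standardize <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("z_standardize() needs finite numeric input", call. = FALSE)
  }
  if (length(unique(x)) < 2L) {
    stop("z_standardize(): constant input; the predictor would be non-estimable",
         call. = FALSE)
  }
  as.numeric((x - mean(x)) / stats::sd(x))
}

# Derive a reproducible 32-bit substream seed from a master seed and a label.
# Each named stage (simulation, permutation, bootstrap, per-participant
# streams) pulls its own seed so stages can be re-run in isolation and adding
# participants never perturbs existing ones.
derive_seed <- function(master, ...) {
  parts <- c(as.character(master), vapply(list(...), as.character, ""))
  h <- 0
  for (ch in utf8ToInt(paste(parts, collapse = "/"))) {
    h <- (h * 31 + ch) %% 2147483629
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
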