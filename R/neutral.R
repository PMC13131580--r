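# Neutral nucleotide mutation models.
#
# A neutral model assigns each nucleotide position a substitution rate and a
# distribution over the 3 alternative bases, as a pure function of the 3-mer
# context centred on the position (sequence ends are padded with A).  It
# stands in for an externally trained context-dependent mutability model: the
# analysis code only touches it through rate / substitution-probability
# lookups, so a trained model could be dropped in behind the same interface.
#
# Kinds:
#   uniform      rate 1 at every position, uniform choice among alternatives
#   context_3mer per-context rate multipliers (log-normal, normalized to mean
#                1 across contexts) and Dirichlet-like substitution biases,
#                drawn reproducibly from the seed

#' Construct a neutral mutation model
#'
#' @param kind `"uniform"` or `"context_3mer"`.
#' @param seed integer seed (required for `context_3mer`).
#' @param rate_sd standard deviation of log rate multipliers across 3-mer
#'   contexts (`context_3mer` only).
#' @return object of class `neutral_model`.
#' @examples
#' m <- make_neutral_model("uniform")
#' neutral_substitution_probs(m, "ACA")
#' @export
make_neutral_model <- function(kind = c("uniform", "context_3mer"),
                               seed = 1L, rate_sd = 0.3) {
  kind <- match.arg(kind)
  contexts <- .ab$codons # all 64 3-mers, same encoding as codons
  if (kind == "uniform") {
    rate64 <- rep(1, 64)
    probs64 <- matrix(1 / 3, 64, 4)
  } else {
    rng <- local({
      set.seed(derive_seed(seed, "neutral_context_3mer"))
      r <- exp(stats::rnorm(64, 0, rate_sd))
      w <- matrix(stats::rgamma(64 * 4, shape = 2), 64, 4)
      list(r = r / mean(r), w = w)
    })
    rate64 <- rng$r
    probs64 <- rng$w
  }
  # zero out the context's own middle base and renormalize rows
  mid <- rep(rep(1:4, each = 4), times = 4) # middle base of context index
  for (i in 1:64) probs64[i, mid[i]] <- 0
  probs64 <- probs64 / rowSums(probs64)
  colnames(probs64) <- .ab_bases
  structure(list(kind = kind, contexts = contexts, rate64 = rate64,
                 probs64 = probs64),
            class = "neutral_model")
}

.context_index <- function(context) {
  idx <- match(toupper(context), .ab$codons)
  if (any(is.na(idx))) stop("context must be a 3-mer over A/C/G/T")
  idx
}

#' Per-position neutral substitution rate
#'
#' @param model a `neutral_model`.
#' @param context 3-mer context string(s), focal base in the middle.
#' @return numeric rate(s), mean 1 across contexts by construction.
#' @export
neutral_rate <- function(model, context) {
  model$rate64[.context_index(context)]
}

#' Conditional substitution probabilities of the focal base
#'
#' @param model a `neutral_model`.
#' @param context a single 3-mer context.
#' @return named numeric over A/C/G/T summing to 1, with probability 0 for
#'   the context's own middle base.
#' @export
neutral_substitution_probs <- function(model, context) {
  model$probs64[.context_index(context), ]
}

# Context index of every position of an integer-encoded sequence, ends
# padded with A (=1).
seq_context_indices <- function(v) {
  n <- length(v)
  left <- c(1L, v[-n])
  right <- c(v[-1L], 1L)
  16L * (left - 1L) + 4L * (v - 1L) + right
}
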