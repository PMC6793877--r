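# Internal helpers shared across modules: seed derivation, bounded-parameter
# transforms, and probability clamping for the log-likelihood.

# Probabilities are clamped away from {0, 1} before logs so that
# near-deterministic parameter vectors keep the likelihood finite.
.p_eps <- 1e-12

clamp_prob <- function(p) pmin(pmax(p, .p_eps), 1 - .p_eps)

# Deterministic per-cell seed derived from a master seed and string labels.
# String hashing (rather than positional indexing) keeps a (subject, model)
# cell's seed stable when other models or subjects are added or removed.
derive_seed <- function(master, ...) {
  labels <- paste(c(...), collapse = "\r")
  codes <- utf8ToInt(labels)
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 2147483563
  as.integer((h + master %% 2147483563) %% 2147483562 + 1)
}

# Logistic transform mapping a box-constrained parameter to the real line,
# used so a derivative-free simplex search respects the fitting bounds.
to_unbounded <- function(x, lower, upper) {
  qlogis((x - lower) / (upper - lower))
}

from_unbounded <- function(z, lower, upper) {
  lower + (upper - lower) * plogis(z)
}

# log(x) * w with the convention 0 * log(0) = 0 (entropy terms).
xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

`%||%` <- function(a, b) if (is.null(a)) b else a
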