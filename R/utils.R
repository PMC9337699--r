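# Small numerical helpers shared across modules.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# per-trial likelihood floor; keeps deterministic heuristics fittable
.lik_eps <- 1e-10

`%||%` <- function(a, b) if (is.null(a)) b else a
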