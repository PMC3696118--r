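# Internal helpers shared across modules.

# Round half away from zero (edge-count quantization for density thresholds).
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Derive a reproducible child seed from a parent seed
#'
#' Every stochastic stage derives per-member / per-sample seeds from one
#' parent seed so that reruns with the same configuration are identical.
#' Seeds stay below 2^31 - 1.
#'
#' @param seed parent integer seed
#' @param i stream index (>= 0)
#' @return an integer seed
#' @export
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483647 + 104729 * (as.numeric(i) %% 20011)) %% 2147483647)
}

# Evaluate `code` under set.seed(seed) without disturbing the caller's RNG
# state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
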