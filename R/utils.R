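# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic small integer offset for a cohort label (keeps seeds < 2^31).
label_offset <- function(label) {
  codes <- utf8ToInt(as.character(label))
  if (length(codes) == 0L) return(0L)
  as.integer(sum(codes * seq_along(codes)) %% 100000L)
}

two_sided_p <- function(z) 2 * stats::pnorm(-abs(z))

# 95% normal-quantile odds-ratio columns shared by every estimator.
or_columns <- function(beta, se) {
  list(or_value = exp(beta),
       ci_low = exp(beta - 1.96 * se),
       ci_high = exp(beta + 1.96 * se))
}
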