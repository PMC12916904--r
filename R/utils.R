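# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL means "use the current RNG stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Derive a stage-specific child seed from a base seed, kept within the
# 32-bit integer range so it is always a valid set.seed() input.
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 1299721) %% 2147483647)
}

clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))

inv_logit <- function(x) plogis(x)
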