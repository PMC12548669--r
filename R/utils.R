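# Internal seeding helpers. Every stochastic function in the package takes an
# explicit `seed`; when given, the global RNG state is saved and restored so
# library calls never perturb a caller's random stream.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-stage seed derivation from one master seed: a fixed
# multiplicative hash reduced modulo 2^31 - 1 (so derived seeds stay valid
# 32-bit R integers). Stage indices must be distinct per call site.
.derive_seed <- function(master, stage) {
  if (is.null(master)) return(NULL)
  as.integer((as.numeric(master) * 48271 + 7919 * as.numeric(stage)) %% 2147483647)
}

.upper_vals <- function(m) m[upper.tri(m)]
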