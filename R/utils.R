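# internal helpers shared across modules

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Round half away from zero to `digits` decimals. base::round() rounds
# half-to-even, which is not how printed volumes like 3.645 -> 3.65 are
# reported; a tiny epsilon guards binary representation of decimal inputs.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# voxel index grids (1-based) for a 3D dim vector, as three arrays
index_grids <- function(dm) {
  list(
    x = array(rep.int(seq_len(dm[1]), dm[2] * dm[3]), dm),
    y = array(rep(seq_len(dm[2]), each = dm[1], times = dm[3]), dm),
    z = array(rep(seq_len(dm[3]), each = dm[1] * dm[2]), dm)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
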