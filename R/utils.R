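# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so simulations compose deterministically.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# "mod00", "mod01", ... labels used throughout module outputs.
module_label <- function(id) sprintf("mod%02d", as.integer(id))

# Deterministic per-stage seed derivation from one pipeline seed. Offsets are
# fixed so stages can be rerun in isolation; kept below 2^31.
stage_seed <- function(seed, stage) {
  offsets <- c(genome = 11L, classes = 23L, counts = 37L, sites = 53L,
               network = 67L, null = 79L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(seed) %% 2000000L) * 1000L + offsets[[stage]]
}

stop_if_not_matrix <- function(x, what = "counts") {
  if (!is.matrix(x)) stop(what, " must be a matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(what, " must have row (gene) and column (sample) names")
  invisible(x)
}
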