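# Internal helpers shared across modules.

# Deterministic sub-stream seeds: one RNG stream per pipeline stage, derived
# from the master seed so adding a stage never perturbs earlier draws.
.stage_offsets <- c(
  cohort = 101L, mirna = 223L, sets = 311L, targets = 419L,
  survival = 521L, gsea = 613L, validation = 709L
)

.stream_seed <- function(seed, stage) {
  off <- .stage_offsets[[stage]]
  as.integer((as.numeric(seed) * 1009 + off) %% 2147483629)
}

# Evaluate fn() under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
.with_stream <- function(seed, fn) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

.assert <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
}

.is_count <- function(x, min = 1) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x == round(x) && x >= min
}

.is_prob <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 0 && x <= 1
}
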