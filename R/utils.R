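# shared internal helpers

# Deterministic child seed for a pipeline stage. One user-facing seed expands
# into per-stage streams so each stage is reproducible in isolation; the
# derivation is a fixed LCG step, kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  stages <- c(sites = 11L, geno = 23L, info = 37L, relatives = 47L,
              sweep = 59L, roh = 71L, depth = 67L, str = 79L, effects = 97L,
              quality = 113L)
  k <- if (is.character(stage)) {
    if (!stage %in% names(stages)) stop("unknown stage: ", stage)
    stages[[stage]]
  } else as.integer(stage)
  s <- as.double(seed %% 65536L)
  as.integer((s * 1103515245 + k * 12345) %% 2147483629)
}

# run a block under a local RNG state so library code never disturbs the
# caller's stream
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

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop("'", name, "' must be a positive finite scalar")
  invisible(x)
}
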