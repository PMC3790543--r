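# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
# A NULL seed runs the code with the ambient RNG untouched.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(eval.parent(substitute(code)))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(code))
}

# Derive a stage seed from a root seed; keeps results < 2^31 and distinct
# across stages so partial re-runs are reproducible.
.stage_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  offsets <- c(signal_sef = 1L, signal_srf = 2L, correlation = 3L,
               filter = 4L, traits = 5L, simulate = 6L)
  off <- if (stage %in% names(offsets)) offsets[[stage]] else
    (sum(utf8ToInt(stage)) %% 1000L)
  as.integer((as.double(seed) * 1009 + off) %% .Machine$integer.max)
}
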