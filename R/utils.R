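# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never clobbers user RNG.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Mix a base seed with a stream index into a valid 32-bit seed, so each fly /
# replicate gets its own reproducible stream. Arithmetic stays in doubles
# below 2^53, result below 2^31 - 1.
mixSeed <- function(seed, index) {
  s <- (abs(as.numeric(seed)) %% 2147483647) + 1
  as.integer((s * 48271 + as.numeric(index) * 1299709) %% 2147483647)
}

stopIfNot1 <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}
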