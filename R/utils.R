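# Internal helpers.

# Evaluate `expr` with a locally seeded RNG, restoring the caller's RNG
# state afterwards. Keeps generators deterministic without clobbering a
# user session's random stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# ppm difference of observed vs theoretical m/z
ppm_error <- function(observed, theoretical) {
  (observed - theoretical) / theoretical * 1e6
}

# stable paste of a character vector for report columns
collapse_tags <- function(x) {
  if (!length(x)) return("")
  paste(x, collapse = ",")
}
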