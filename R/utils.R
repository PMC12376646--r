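# Run code with a temporary RNG seed, restoring global RNG state afterwards.
with_preserved_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
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
  force(code)
}

# labeled (i >= 1) fractions of an ffa_mid as a plain vector
labeled_fractions <- function(m) {
  stopifnot(inherits(m, "ffa_mid"))
  m$fractions[-1L]
}
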