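# small internal helpers

# run `expr` under a fixed RNG seed and restore the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

is_scalar_int <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

abort_sonoseg <- function(msg, class = "sonoseg_error") {
  rlang::abort(msg, class = class)
}
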