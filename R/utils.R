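# Evaluate expr with a temporary RNG state when seed is given; the caller's
# RNG stream is untouched either way.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Well labels in row-major plate order: A1..A12, B1..B12, ..., H1..H12.
well_labels_96 <- function() {
  as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
}

is_well_label <- function(x) {
  grepl("^[A-H](1[0-2]|[1-9])$", x)
}
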