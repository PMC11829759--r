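# run expr with a locally seeded RNG, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.assert_unit_vector <- function(v, name) {
  if (length(v) != 3L || abs(sqrt(sum(v^2)) - 1) > 1e-6) {
    stop(sprintf("`%s` must be a 3D unit vector", name), call. = FALSE)
  }
  invisible(v)
}
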