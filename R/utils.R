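## small internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert_scalar_num <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    stop(sprintf("`%s` must be a single finite numeric value", name),
         call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  invisible(x)
}

.rms <- function(x) sqrt(mean(x^2))

## Run `expr` under a temporary RNG state seeded with `seed`; the caller's
## .Random.seed is restored afterwards so library code never clobbers it.
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

.format_num <- function(x) formatC(x, digits = 9, format = "g")
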