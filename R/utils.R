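# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_positive <- function(x, field) {
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x)) || any(x <= 0))
    stop_validation(field, "must be finite and > 0")
  invisible(x)
}

check_nonnegative <- function(x, field) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0))
    stop_validation(field, "must be finite and >= 0")
  invisible(x)
}

# inverse complementary error function via the normal quantile
erfc_inv <- function(q) {
  if (any(q <= 0 | q >= 2)) stop("erfc_inv: argument must lie in (0, 2)")
  stats::qnorm(1 - q / 2) / sqrt(2)
}

erfc <- function(x) 2 * stats::pnorm(-sqrt(2) * x)

# run expr with a local RNG state seeded by `seed` (NULL = use current stream)
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# dB SPL (re 20 uPa) <-> sinusoid peak amplitude in Pa
spl_to_pa <- function(level_db) sqrt(2) * 20e-6 * 10^(level_db / 20)
pa_to_spl <- function(amp_pa) 20 * log10(pmax(amp_pa, .Machine$double.xmin) / sqrt(2) / 20e-6)
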