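# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards so library code never perturbs user simulations.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Fixed per-component seed offsets: one root seed per animal, children derived
# by constant offsets so each signal component can be regenerated independently.
SEED_OFFSET_SCHEDULE <- 0L
SEED_OFFSET_IMU <- 100003L
SEED_OFFSET_TEMP <- 200003L

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Check a timestamp vector for uniform sampling within a relative tolerance.
check_uniform <- function(t_s, rtol = 1e-6, what = "series") {
  if (length(t_s) < 2L) {
    return(invisible(TRUE))
  }
  d <- diff(t_s)
  if (any(d <= 0)) stopf("%s timestamps must be strictly increasing", what)
  dm <- stats::median(d)
  if (any(abs(d - dm) > rtol * dm)) {
    stopf("%s is not uniformly sampled (spacing varies beyond tolerance)", what)
  }
  invisible(TRUE)
}
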