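# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG seeded with `seed`, restoring the caller's
# RNG state afterwards.  All seeded entry points route through this so that
# library calls never perturb a user's random stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed < 0)
    stop("seed must be a single non-negative integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# Derive a child seed from a parent seed and a stream label, keeping the
# result inside the 32-bit integer range.
child_seed <- function(seed, ...) {
  parts <- unlist(lapply(list(...), function(p) {
    if (is.character(p)) sum(utf8ToInt(p)) else as.numeric(p)
  }))
  as.integer((as.numeric(seed) * 7919 + sum(parts * 104729)) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_binary <- function(x, what = "mask") {
  u <- unique(as.vector(x))
  if (!all(u %in% c(0L, 1L, 0, 1)))
    stopf("%s must contain only values 0 and 1", what)
  invisible(TRUE)
}

# Half-up decimal rounding for report display (R's round() is half-even and
# representation-sensitive: round(1.675, 2) gives 1.67).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # the epsilon absorbs binary representation error (1.675 is stored just
  # below its decimal value)
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# 3D outer sum a_i + b_j + c_k without forming intermediate copies twice.
outer_sum3 <- function(a, b, c) {
  x <- outer(a, b, "+")
  outer(x, c, "+")
}
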