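# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream.  All user-facing stochastic entry points go through this so that
# identical (config, seed) pairs give bit-identical output.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Dilate a logical mask by `pad_n` samples on each side.
dilate_mask <- function(mask, pad_n) {
  if (pad_n <= 0 || !any(mask)) return(mask)
  n <- length(mask)
  cs <- cumsum(as.integer(mask))
  lo <- pmax(seq_len(n) - pad_n, 1L)
  hi <- pmin(seq_len(n) + pad_n, n)
  # count of masked samples in [lo, hi] > 0
  (cs[hi] - cs[lo] + as.integer(mask[lo])) > 0L
}

# Raised-cosine event profile: 0 at u <= 0, rises to 1 at u = t_nadir,
# returns to 0 at u = t_recover, 0 after.  Used for HR/SpO2 dips.
raised_cosine_dip <- function(u, t_nadir = 30, t_recover = 90) {
  w <- numeric(length(u))
  i1 <- u > 0 & u <= t_nadir
  w[i1] <- (1 - cos(pi * u[i1] / t_nadir)) / 2
  i2 <- u > t_nadir & u < t_recover
  w[i2] <- (1 + cos(pi * (u[i2] - t_nadir) / (t_recover - t_nadir))) / 2
  w
}

# Do two half-open intervals [s1, e1) and [s2, e2) overlap?
intervals_overlap <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
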