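## Internal helpers shared across modules.

## Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
## the caller's .Random.seed afterwards so library calls never perturb user
## simulations.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

## Deterministic stream of child seeds, kept below 2^31 - 1.
derive_seed <- function(master_seed, i, j = 0L) {
  m <- as.double(master_seed) %% 1e6
  s <- (m * 2654435.0 + as.double(i) * 40503.0 + as.double(j) * 97.0) %% 2147483646
  as.integer(s) + 1L
}

## Population (divide-by-n) variance, consistent with the biased
## autocorrelation estimate used by the AR identification.
pop_var <- function(x) {
  mean((x - mean(x))^2)
}

## Remove the least-squares linear trend (including the mean).
lin_detrend <- function(x) {
  n <- length(x)
  t0 <- seq_len(n) - (n + 1) / 2
  x - mean(x) - t0 * (sum(t0 * x) / sum(t0 * t0))
}

## Sliding maximum of `v` over a trailing window of `w` samples (window
## [i - w + 1, i], truncated at the start). O(n) block prefix/suffix scheme.
trailing_max <- function(v, w) {
  n <- length(v)
  if (w >= n) {
    return(cummax(v))
  }
  nb <- ceiling(n / w)
  vp <- c(v, rep(-Inf, nb * w - n))
  m <- matrix(vp, nrow = w)
  pre <- apply(m, 2L, cummax)
  suf <- apply(m[w:1, , drop = FALSE], 2L, cummax)[w:1, , drop = FALSE]
  out <- numeric(n)
  i <- seq_len(n)
  left <- i - w + 1L
  out <- ifelse(left < 1L, pre[i], NA_real_)
  ok <- left >= 1L
  out[ok] <- pmax(suf[left[ok]], pre[i[ok]])
  out
}

## Trapezoidal quadrature on a uniform grid.
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
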