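#' Linearly detrend and z-score a beat series
#'
#' Removes the least-squares linear trend (which removes the mean), then
#' scales to unit variance (population convention). This is the
#' normalisation applied to HP, SAP and RESP series before bivariate
#' identification, and it makes all K2/CK2 markers invariant to the scale
#' and offset of the input series.
#'
#' @param x Numeric beat series.
#' @return Numeric series with mean 0 and variance 1 (to within 1e-10).
#' @export
#' @examples
#' z <- normalize_series(sin(2 * pi * 0.1 * 1:256) + 0.01 * 1:256)
#' c(mean(z), mean(z^2))
normalize_series <- function(x) {
  if (!is.numeric(x) || length(x) < 4L) {
    stop("series must be numeric with length >= 4", call. = FALSE)
  }
  xd <- lin_detrend(x)
  v <- mean(xd^2)
  if (v <= .Machine$double.eps * max(1, mean(x^2))) {
    stop("degenerate series: zero variance after detrending", call. = FALSE)
  }
  xd / sqrt(v)
}

## Regressor matrix for one equation of the bivariate model.
## own channel enters at lags 1..p, the other channel at lags k_min..p.
## Rows are aligned at `align` (>= p) so that lag `align` is available.
bar_design <- function(own, other, p, k_min, align) {
  n <- length(own)
  rows <- (align + 1L):n
  N <- length(rows)
  X_own <- matrix(own[rep.int(rows, p) - rep(1:p, each = N)], N, p)
  n_oth <- p - k_min + 1L
  X_oth <- matrix(other[rep.int(rows, n_oth) - rep(k_min:p, each = N)], N, n_oth)
  list(X = cbind(X_own, X_oth), rows = rows, n_own = p)
}

## Cholesky least squares on the normal equations; pivoted fallback when the
## Gram matrix is numerically near-singular.
chol_lsq <- function(X, y) {
  G <- crossprod(X)
  b <- crossprod(X, y)
  R <- tryCatch(chol(G), error = function(e) NULL)
  if (is.null(R) || kappa(R, exact = FALSE)^2 > 1e12) {
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) stop("identification failure: rank-deficient regressor matrix",
                                 call. = FALSE)
    warning("near-singular normal equations; using pivoted QR solve", call. = FALSE)
    return(qr.coef(qrX, y))
  }
  drop(backsolve(R, forwardsolve(t(R), b)))
}

#' Fit a bivariate autoregressive (BAR) model with directional latencies
#'
#' Identifies the two-channel autoregressive model
#' \deqn{x(n) = \sum_k a_{xx}(k) x(n-k) + \sum_{k \ge k_{yx}} a_{xy}(k) y(n-k) + w_x(n)}
#' \deqn{y(n) = \sum_k a_{yy}(k) y(n-k) + \sum_{k \ge k_{xy}} a_{yx}(k) x(n-k) + w_y(n)}
#' by per-equation least squares solved via Cholesky factorisation of the
#' normal equations. The latency pair sets the minimum cross-regression lag
#' per direction; at most one direction may act at lag 0 (instantaneous), and
#' the innovation covariance is taken diagonal because the instantaneous
#' dependence is modelled explicitly by the lag-0 coefficient.
#'
#' The common model order for both equations minimises the multivariate
#' Akaike figure of merit `N*log(lambda_x*lambda_y) + 2*n_coef` over
#' `order_range`, evaluated on the common sample aligned at the maximum
#' candidate order; the selected model is then re-estimated on all usable
#' rows.
#'
#' @param x,y Numeric series of equal length (normalise with
#'   [normalize_series()] first for coherence analysis).
#' @param order_range `c(min, max)` candidate orders, default `c(5, 14)`.
#' @param latency `c(k_xy, k_yx)`: minimum lag from x to y and from y to x.
#'   Must be one of `(0,1)`, `(1,0)`, `(1,1)`. E.g. for the HP-RESP pair with
#'   `x = RESP`, `y = HP`, the conventional choice is `c(0, 1)` (RESP acts on
#'   HP within the same beat, HP on RESP one beat later).
#' @param labels Channel names, used by print methods.
#' @return Object of class `bar_model`: coefficient array `A` (2 x 2 x
#'   (p+1); `A[i, j, k+1]` multiplies channel j at lag k in the equation of
#'   channel i), innovation variances `lambda`, selected `order`, `stable`
#'   flag, residuals, AIC table.
#' @export
#' @examples
#' x <- rnorm(512); y <- 0.8 * c(0, head(x, -1)) + rnorm(512)
#' m <- fit_bar(normalize_series(x), normalize_series(y), latency = c(1, 1))
#' m$order
fit_bar <- function(x, y, order_range = c(5L, 14L), latency = c(0L, 1L),
                    labels = c("x", "y")) {
  if (length(x) != length(y)) stop("series must have equal length", call. = FALSE)
  order_range <- as.integer(order_range)
  latency <- as.integer(latency)
  if (!paste(latency, collapse = ",") %in% c("0,1", "1,0", "1,1")) {
    stop("latency must be one of (0,1), (1,0), (1,1)", call. = FALSE)
  }
  p_min <- min(order_range); p_max <- max(order_range)
  n <- length(x)
  if (n < 4L * p_max) {
    stop("series too short: need at least ", 4L * p_max, " samples", call. = FALSE)
  }
  k_xy <- latency[1L]  # min lag of x in y's equation
  k_yx <- latency[2L]  # min lag of y in x's equation

  fit_order <- function(p, align) {
    dx <- bar_design(x, y, p, k_yx, align)
    dy <- bar_design(y, x, p, k_xy, align)
    cx <- chol_lsq(dx$X, x[dx$rows])
    cy <- chol_lsq(dy$X, y[dy$rows])
    rx <- x[dx$rows] - drop(dx$X %*% cx)
    ry <- y[dy$rows] - drop(dy$X %*% cy)
    list(p = p, cx = cx, cy = cy,
         lambda = c(mean(rx^2), mean(ry^2)),
         resid = cbind(rx, ry),
         n_used = length(dx$rows),
         n_coef = length(cx) + length(cy))
  }

  ## Order scan on the common sample aligned at p_max; residual variances for
  ## every candidate order come from sub-blocks of the single max-order Gram
  ## matrix (rss = y'y - b'coef for the normal-equations solution).
  orders <- p_min:p_max
  scan_eq <- function(own, other, k_min) {
    d <- bar_design(own, other, p_max, k_min, p_max)
    G <- crossprod(d$X)
    b <- drop(crossprod(d$X, own[d$rows]))
    yty <- sum(own[d$rows]^2)
    N <- length(d$rows)
    vapply(orders, function(p) {
      sel <- c(1:p, p_max + seq_len(p - k_min + 1L))
      co <- tryCatch({
        R <- chol(G[sel, sel])
        backsolve(R, forwardsolve(t(R), b[sel]))
      }, error = function(e) NULL)
      if (is.null(co)) return(c(NA_real_, NA_real_))
      c((yty - sum(b[sel] * co)) / N, length(sel))
    }, numeric(2))
  }
  sx <- scan_eq(x, y, k_yx)
  sy <- scan_eq(y, x, k_xy)
  N_scan <- n - p_max
  aic <- N_scan * log(sx[1L, ] * sy[1L, ]) + 2 * (sx[2L, ] + sy[2L, ])
  aic[!is.finite(aic)] <- Inf
  if (all(aic == Inf)) stop("identification failure: rank-deficient regressor matrix",
                            call. = FALSE)
  p_sel <- orders[which.min(aic)]
  fit <- fit_order(p_sel, p_sel)

  A <- array(0, dim = c(2L, 2L, p_sel + 1L))
  A[1L, 1L, 2:(p_sel + 1L)] <- fit$cx[1:p_sel]
  A[1L, 2L, (k_yx + 1L):(p_sel + 1L)] <- fit$cx[(p_sel + 1L):length(fit$cx)]
  A[2L, 2L, 2:(p_sel + 1L)] <- fit$cy[1:p_sel]
  A[2L, 1L, (k_xy + 1L):(p_sel + 1L)] <- fit$cy[(p_sel + 1L):length(fit$cy)]

  model <- structure(list(
    A = A, order = p_sel, lambda = stats::setNames(fit$lambda, labels),
    latency = c(x_to_y = k_xy, y_to_x = k_yx),
    labels = labels, n = n, n_used = fit$n_used,
    aic = stats::setNames(aic, orders),
    residuals = fit$resid
  ), class = "bar_model")
  model$stable <- bar_stable(model)
  model
}

## Stability via the companion matrix of the reduced form
## (I - A0)^-1 applied to the lagged coefficient blocks.
bar_stable <- function(model) {
  A <- model$A
  p <- model$order
  A0 <- A[, , 1L]
  M0 <- solve(diag(2) - A0)
  comp <- matrix(0, 2L * p, 2L * p)
  for (k in seq_len(p)) {
    comp[1:2, (2L * k - 1L):(2L * k)] <- M0 %*% A[, , k + 1L]
  }
  if (p > 1L) comp[3:(2L * p), 1:(2L * p - 2L)] <- diag(2L * p - 2L)
  all(Mod(eigen(comp, only.values = TRUE)$values) < 1)
}

#' @export
print.bar_model <- function(x, ...) {
  cat(sprintf("Bivariate AR model (%s, %s): order %d, latency (%d, %d)\n",
              x$labels[1], x$labels[2], x$order,
              x$latency[1], x$latency[2]))
  cat(sprintf("innovation variances: %.4g (%s), %.4g (%s)%s\n",
              x$lambda[1], x$labels[1], x$lambda[2], x$labels[2],
              if (x$stable) "" else "  [UNSTABLE]"))
  invisible(x)
}

#' @export
coef.bar_model <- function(object, ...) object$A

#' @export
residuals.bar_model <- function(object, ...) object$residuals

#' Simulate realizations from a fitted bivariate AR model
#'
#' Draws Gaussian innovations with the fitted (diagonal) innovation variances
#' and runs the model recursion, respecting the instantaneous pathway: the
#' channel receiving a lag-0 regressor is generated after its driver within
#' each beat. Used mainly as a long-run oracle for coherence estimates.
#'
#' @param object A stable `bar_model`.
#' @param nsim Length of each realization (beats).
#' @param seed Optional integer seed (RNG state is restored on exit).
#' @param burn_in Beats discarded at the start.
#' @param ... Unused.
#' @return A `nsim` x 2 matrix with columns named after the model channels.
#' @export
simulate.bar_model <- function(object, nsim = object$n, seed = NULL,
                               burn_in = 256L, ...) {
  if (!object$stable) stop("refusing to simulate from an unstable model", call. = FALSE)
  gen <- function() {
    A <- object$A; p <- object$order
    ntot <- nsim + burn_in
    w <- cbind(rnorm(ntot, sd = sqrt(object$lambda[1])),
               rnorm(ntot, sd = sqrt(object$lambda[2])))
    z <- matrix(0, ntot, 2L)
    ## lag-0 dependence: at most one of A[1,2,1], A[2,1,1] is nonzero
    first <- if (A[1L, 2L, 1L] != 0) 2L else 1L
    second <- 3L - first
    for (n in (p + 1L):ntot) {
      for (i in c(first, second)) {
        j <- 3L - i
        acc <- w[n, i]
        for (k in seq_len(p)) {
          acc <- acc + A[i, i, k + 1L] * z[n - k, i] + A[i, j, k + 1L] * z[n - k, j]
        }
        acc <- acc + A[i, j, 1L] * z[n, j]
        z[n, i] <- acc
      }
    }
    z <- z[(burn_in + 1L):ntot, , drop = FALSE]
    colnames(z) <- object$labels
    z
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}
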