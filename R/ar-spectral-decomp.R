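#' Residue-theorem spectral decomposition of an AR model
#'
#' Factorises the parametric power spectral density of a stable AR model into
#' one spectral component per real pole and per complex-conjugate pole pair.
#' The power of each component is the residue of `S(z)/z` at the pole
#' (doubled for a conjugate pair), so the component powers sum to the
#' modelled process variance. The central frequency of a component is the
#' pole angle in cycles/beat, converted to Hz by dividing by the segment's
#' mean heart period in seconds.
#'
#' Real positive poles map to 0 Hz and real negative poles to the beat-domain
#' Nyquist frequency; both fall outside the LF and HF bands and are therefore
#' never counted by [band_power()]. Components whose residue power comes out
#' numerically negative (possible with near-cancelling poles) are clipped at
#' zero and flagged in the `clipped` column (with a warning when the clipped
#' mass exceeds 1% of the process variance); the signed residue
#' power is kept in `power_signed`, whose sum over components equals the
#' modelled process variance exactly.
#'
#' @param model A stable `ar_model` from [fit_ar()].
#' @return A data frame of class `spectral_components` with columns
#'   `central_frequency_hz`, `central_frequency_cpb`, `power` (clipped at 0),
#'   `power_signed`, `pole_modulus`, `is_real_pole`, `clipped`.
#' @export
#' @examples
#' m <- fit_ar(as.numeric(arima.sim(list(ar = c(1.2, -0.8)), 1024)))
#' decompose_spectrum(m)
decompose_spectrum <- function(model) {
  stopifnot(inherits(model, "ar_model"))
  if (!model$stable) stop("unstable AR model", call. = FALSE)
  a <- model$coefficients
  p <- model$order
  sigma2 <- model$sigma2_w
  poles <- model$poles
  ## A(z) = 1 - sum a_k z^-k and its derivative in z
  A_of <- function(z) 1 - vapply(z, function(zz) sum(a * zz^-(1:p)), complex(1))
  dA_of <- function(z) vapply(z, function(zz) sum((1:p) * a * zz^-(2:(p + 1))), complex(1))

  ## keep one representative per conjugate pair: Im >= 0
  tol <- 1e-9 * max(1, Mod(poles))
  keep <- Im(poles) > tol | abs(Im(poles)) <= tol
  reps <- poles[keep]
  is_real <- abs(Im(reps)) <= tol

  res <- sigma2 / (reps * dA_of(reps) * A_of(1 / reps))
  power_signed <- ifelse(is_real, Re(res), 2 * Re(res))
  clipped <- power_signed < 0
  power <- pmax(power_signed, 0)
  ## tiny negative residues are routine with orders 8-14; only a clipped mass
  ## that visibly distorts the band powers deserves a warning
  if (any(clipped) &&
      sum(-power_signed[clipped]) > 0.01 * sum(abs(power_signed))) {
    warning("clipped ", sum(clipped),
            " negative residue power(s) at 0 (near-cancelling poles)",
            call. = FALSE)
  }
  f_cpb <- abs(Arg(reps)) / (2 * pi)
  out <- data.frame(
    central_frequency_hz = f_cpb / model$mean_hp_s,
    central_frequency_cpb = f_cpb,
    power = power,
    power_signed = power_signed,
    pole_modulus = Mod(reps),
    is_real_pole = is_real,
    clipped = clipped
  )
  out <- out[order(out$central_frequency_hz), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("spectral_components", "data.frame")
  out
}

#' Band power from spectral components
#'
#' Sums the powers of the spectral components whose central frequency lies in
#' the closed-open band `[lo, hi)`.
#'
#' @param components A `spectral_components` data frame from
#'   [decompose_spectrum()].
#' @param band Numeric `c(lo, hi)` in Hz, e.g. `lf_hf_bands()$hf`.
#' @return Scalar power in series units squared (0 if no component in band).
#' @export
band_power <- function(components, band) {
  stopifnot(is.numeric(band), length(band) == 2L, band[1] < band[2])
  f <- components$central_frequency_hz
  sum(components$power[f >= band[1] & f < band[2]])
}

#' Respiratory frequency from RESP spectral components
#'
#' The respiratory rate is the central frequency of the largest-power
#' spectral component of the respiration series inside the HF band,
#' expressed in breaths per minute. Ties are broken towards the lower
#' frequency.
#'
#' @param components `spectral_components` of the RESP series.
#' @param hf Numeric `c(lo, hi)` HF band in Hz.
#' @return Respiratory frequency in breaths/min.
#' @export
resp_frequency <- function(components, hf = lf_hf_bands()$hf) {
  f <- components$central_frequency_hz
  in_hf <- f >= hf[1] & f < hf[2]
  if (!any(in_hf)) stop("no respiratory component in HF band", call. = FALSE)
  sub <- components[in_hf, , drop = FALSE]
  sub <- sub[order(-sub$power, sub$central_frequency_hz), , drop = FALSE]
  60 * sub$central_frequency_hz[1L]
}
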