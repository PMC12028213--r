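#' Arterial input function (AIF)
#'
#' Population plasma concentration curves Cp(t) driving the Tofts model.
#' Three models are available:
#'
#' * `"weinmann"` (default): biexponential decay
#'   \eqn{Cp(t) = Dose (a_1 e^{-m_1 t} + a_2 e^{-m_2 t})} with the classic
#'   population constants \eqn{a_1 = 3.99, a_2 = 4.78} kg/L,
#'   \eqn{m_1 = 0.144, m_2 = 0.0111} min\eqn{^{-1}}, multiplied by a short
#'   bolus-arrival ramp \eqn{1 - e^{-t/\tau}} (\eqn{\tau} = 8 s) so that
#'   Cp(0) = 0.
#' * `"parker"`: population mixture of two Gaussians plus a sigmoid-modulated
#'   exponential.
#' * `"boxcar"`: rectangular bolus of height `c0` on `[t0, t1]` seconds —
#'   used in tests because its Tofts convolution has a closed form.
#'
#' @param model AIF model name.
#' @param dose Contrast dose in mmol/kg (weinmann).
#' @param ramp_tau Bolus-arrival ramp time constant in seconds (weinmann).
#' @param c0,t0,t1 Boxcar height (mmol/L) and start/end times (seconds).
#' @return An object of class `aif`.
#' @export
aif <- function(model = c("weinmann", "parker", "boxcar"),
                dose = 0.1, ramp_tau = 8, c0 = 1, t0 = 10, t1 = 70) {
  model <- match.arg(model)
  structure(list(model = model, dose = dose, ramp_tau = ramp_tau,
                 c0 = c0, t0 = t0, t1 = t1),
            class = "aif")
}

#' Evaluate an AIF
#'
#' @param x An [aif()].
#' @param t Times in seconds, `>= 0`.
#' @return Plasma concentration Cp(t) in mmol/L; Cp(0) = 0 and Cp >= 0.
#' @export
aif_eval <- function(x, t) {
  stopifnot(inherits(x, "aif"), all(t >= 0))
  tm <- t / 60  # minutes
  cp <- switch(x$model,
    weinmann = {
      biexp <- x$dose * (3.99 * exp(-0.144 * tm) + 4.78 * exp(-0.0111 * tm))
      ramp <- if (x$ramp_tau > 0) 1 - exp(-t / x$ramp_tau) else as.numeric(t > 0)
      biexp * ramp
    },
    parker = {
      # Population AIF: two Gaussian boluses + sigmoid-gated exponential washout
      A1 <- 0.809; A2 <- 0.330; T1 <- 0.17046; T2 <- 0.365
      s1 <- 0.0563; s2 <- 0.132
      a <- 1.050; beta <- 0.1685; s <- 38.078; tau <- 0.483
      g1 <- A1 / (s1 * sqrt(2 * pi)) * exp(-(tm - T1)^2 / (2 * s1^2))
      g2 <- A2 / (s2 * sqrt(2 * pi)) * exp(-(tm - T2)^2 / (2 * s2^2))
      wash <- a * exp(-beta * tm) / (1 + exp(-s * (tm - tau)))
      pmax(g1 + g2 + wash, 0)
    },
    boxcar = ifelse(t >= x$t0 & t <= x$t1, x$c0, 0)
  )
  # Cp(0) = 0 invariant (parker's washout tail is numerically ~0 at t=0)
  cp[t == 0] <- 0
  pmax(cp, 0)
}
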