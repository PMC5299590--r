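# Melting-point estimators: the Gold-Ogle boiling-point rule, a
# variance-stabilized (square-root Anscombe transform) regression of
# melting temperature on the intermolecular lattice energy, and the
# average of the two estimators.

#' Gold-Ogle melting-point rule
#'
#' Estimates the melting temperature from the boiling temperature as
#' `T_m = 0.5839 * T_b`.
#'
#' @param t_boil Boiling temperature(s), K (> 0).
#' @return Estimated melting temperature(s), K.
#' @examples
#' gold_ogle(500)  # 291.95
#' @export
gold_ogle <- function(t_boil) {
  if (any(t_boil <= 0)) stop_value("boiling temperature must be positive")
  0.5839 * t_boil
}

#' Fit a melting-point regression on intermolecular energies
#'
#' A straight proportionality between melting points and lattice energies
#' does not hold; after a variance-stabilizing square-root (Anscombe)
#' transformation of the (negative) intermolecular energy an ordinary
#' linear fit does: `T_m = beta0 + beta1 * sqrt(-E_inter)`.
#'
#' @param e_inter Intermolecular energies, kJ mol^-1, all negative.
#' @param t_m Experimental melting temperatures, K.
#' @return Object of class `melting_model`: `beta0` (K), `beta1`
#'   (K (kJ/mol)^-1/2), `residual_sd` (K), `n_fit`, and the underlying
#'   `lm` fit.
#' @export
fit_melting_model <- function(e_inter, t_m) {
  if (length(e_inter) != length(t_m)) {
    stop_value("e_inter and t_m must have equal length")
  }
  if (length(t_m) < 3) stop_value("need at least 3 observations")
  if (any(e_inter >= 0)) {
    stop_value("all intermolecular energies must be negative (bound crystals)")
  }
  x <- sqrt(-e_inter)
  if (stats::sd(x) < 1e-12) stop_value("constant predictor; cannot fit")
  fit <- stats::lm(t_m ~ x)
  structure(list(beta0 = unname(coef(fit)[1]), beta1 = unname(coef(fit)[2]),
                 residual_sd = summary(fit)$sigma, n_fit = length(t_m),
                 fit = fit),
            class = "melting_model")
}

#' @export
print.melting_model <- function(x, ...) {
  cat(sprintf(
    "melting model: T_m = %.2f + %.3f * sqrt(-E_inter)  [n = %d, residual sd %.1f K]\n",
    x$beta0, x$beta1, x$n_fit, x$residual_sd))
  invisible(x)
}

#' Predict melting temperatures from a fitted model
#'
#' @param object A `melting_model`.
#' @param e_inter Intermolecular energies, kJ mol^-1 (negative).
#' @param ... Unused.
#' @return Predicted melting temperatures, K.
#' @export
predict.melting_model <- function(object, e_inter, ...) {
  if (any(e_inter >= 0)) stop_value("E_inter must be negative")
  object$beta0 + object$beta1 * sqrt(-e_inter)
}

#' Combine a fragment-based and a regression melting estimate
#'
#' The final predicted melting temperature is the arithmetic mean of a
#' molecular-fragment estimate (supplied externally) and the
#' energy-regression estimate. If one of the two is missing (`NA`), the
#' other is returned with a warning.
#'
#' @param fragment_tm Fragment-contribution estimate, K.
#' @param model_tm Regression-model estimate, K.
#' @return Combined estimate, K.
#' @export
combined_estimate <- function(fragment_tm, model_tm) {
  miss_f <- is.na(fragment_tm); miss_m <- is.na(model_tm)
  if (miss_f && miss_m) stop_value("both melting estimates missing")
  if (miss_f || miss_m) {
    warning("one melting estimate missing; falling back to the other",
            call. = FALSE)
    return(if (miss_f) model_tm else fragment_tm)
  }
  if (fragment_tm <= 0 || model_tm <= 0) {
    stop_value("melting estimates must be positive")
  }
  (fragment_tm + model_tm) / 2
}
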