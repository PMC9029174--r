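#' Residual-error model
#'
#' Heteroscedastic residual model built on the assay-error polynomial
#' `SD_poly(C) = C0 + C1 * C`. In multiplicative (`"gamma"`) mode the total
#' residual SD is `gamma * SD_poly(C)`; in additive (`"lambda"`) mode it is
#' `sqrt(SD_poly(C)^2 + lambda^2)`. The final piperacillin model uses the
#' multiplicative form `5 * (1 + 0.1 * C)`, i.e. `C0 = 1`, `C1 = 0.1`,
#' `gamma = 5`.
#'
#' @param C0 Intercept of the SD polynomial, mg/L.
#' @param C1 Slope of the SD polynomial (dimensionless).
#' @param mode `"gamma"` (multiplicative) or `"lambda"` (additive).
#' @param gamma Multiplicative scale factor (used when `mode = "gamma"`).
#' @param lambda Additive SD, mg/L (used when `mode = "lambda"`).
#' @return An object of class `error_model`.
#' @examples
#' error_model() # the final piperacillin residual model, SD = 5 * (1 + 0.1 C)
#' @export
error_model <- function(C0 = 1, C1 = 0.1, mode = c("gamma", "lambda"),
                        gamma = 5, lambda = 0) {
  mode <- match.arg(mode)
  if (C0 <= 0 && C1 <= 0) stop("SD polynomial must be positive for C >= 0")
  if (C0 < 0) stop("`C0` must be >= 0")
  if (mode == "gamma" && gamma <= 0) stop("`gamma` must be positive")
  if (mode == "lambda" && lambda < 0) stop("`lambda` must be >= 0")
  structure(
    list(C0 = C0, C1 = C1, mode = mode, gamma = gamma, lambda = lambda),
    class = "error_model"
  )
}

#' @export
print.error_model <- function(x, ...) {
  if (x$mode == "gamma") {
    cat(sprintf("<error_model> SD(C) = %.4g * (%.4g + %.4g C) mg/L\n",
                x$gamma, x$C0, x$C1))
  } else {
    cat(sprintf("<error_model> SD(C) = sqrt((%.4g + %.4g C)^2 + %.4g^2) mg/L\n",
                x$C0, x$C1, x$lambda))
  }
  invisible(x)
}

#' Residual standard deviation at a concentration
#'
#' @param concentration Concentration(s), mg/L, `>= 0`.
#' @param model An [error_model()].
#' @return Residual SD in mg/L (vectorized).
#' @examples
#' residual_sd(40, error_model()) # 5 * (1 + 4) = 25 mg/L
#' @export
residual_sd <- function(concentration, model = error_model()) {
  stopifnot(inherits(model, "error_model"))
  if (any(concentration < 0)) stop("concentration must be >= 0")
  sd_poly <- model$C0 + model$C1 * concentration
  out <- if (model$mode == "gamma") {
    model$gamma * sd_poly
  } else {
    sqrt(sd_poly^2 + model$lambda^2)
  }
  if (any(out <= 0)) stop("residual SD must be positive; check the error model")
  out
}
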