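#' Structural pharmacokinetic parameters
#'
#' Bundle the parameters of the one- or two-compartment disposition model with
#' linear elimination from the central compartment: clearance `CL` (L/h),
#' central volume `V` (L), and the first-order distribution rate constants
#' `KCP` (central to peripheral, 1/h) and `KPC` (peripheral to central, 1/h).
#' Setting `KCP = KPC = 0` reduces the model to one compartment.
#'
#' @param CL Clearance in L/h. Must be positive.
#' @param V Central volume of distribution in L. Must be positive.
#' @param KCP Central-to-peripheral rate constant in 1/h, `>= 0`.
#' @param KPC Peripheral-to-central rate constant in 1/h, `>= 0`.
#'
#' @return An object of class `pk_params` (a named list).
#' @examples
#' pk_params(CL = 3.33, V = 10.69, KCP = 1.15, KPC = 0.08)
#' @export
pk_params <- function(CL, V, KCP = 0, KPC = 0) {
  stopifnot(length(CL) == 1, length(V) == 1, length(KCP) == 1, length(KPC) == 1)
  if (!is.finite(CL) || CL <= 0) stop("`CL` must be a positive number (L/h).")
  if (!is.finite(V) || V <= 0) stop("`V` must be a positive number (L).")
  if (!is.finite(KCP) || KCP < 0) stop("`KCP` must be >= 0 (1/h).")
  if (!is.finite(KPC) || KPC < 0) stop("`KPC` must be >= 0 (1/h).")
  structure(list(CL = CL, V = V, KCP = KCP, KPC = KPC), class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat(sprintf(
    "<pk_params> CL = %.4g L/h, V = %.4g L, KCP = %.4g 1/h, KPC = %.4g 1/h\n",
    x$CL, x$V, x$KCP, x$KPC
  ))
  invisible(x)
}

#' Hybrid (macro) rate constants of the two-compartment model
#'
#' Computes the bi-exponential hybrid rate constants alpha and beta from the
#' micro constants, defined by `alpha + beta = ke + KCP + KPC` and
#' `alpha * beta = ke * KPC` with `ke = CL / V`. For a one-compartment model
#' (`KCP = KPC = 0`) this returns `(ke, 0)`.
#'
#' @param params A [pk_params()] object.
#' @return A named numeric vector `c(alpha =, beta =)`, in 1/h, with
#'   `alpha >= beta >= 0`.
#' @examples
#' macro_constants(pk_params(CL = 3.33, V = 10.69, KCP = 1.15, KPC = 0.08))
#' @export
macro_constants <- function(params) {
  stopifnot(inherits(params, "pk_params"))
  ke <- params$CL / params$V
  ab <- .hybrid_constants(ke, params$KCP, params$KPC)
  c(alpha = ab$alpha, beta = ab$beta)
}

# Vectorized hybrid constants with a guard against the (measure-zero)
# repeated-root case alpha == beta, which the Lagrange-interpolation matrix
# exponential cannot represent.
.hybrid_constants <- function(ke, kcp, kpc) {
  s <- ke + kcp + kpc
  disc2 <- s^2 - 4 * ke * kpc
  disc2[disc2 < 0] <- 0
  disc <- sqrt(disc2)
  close <- disc < 1e-9 * s
  if (any(close)) {
    # nudge kpc to split the repeated root; relative error O(1e-8)
    kpc2 <- kpc * (1 + 1e-7) + 1e-12
    s[close] <- (ke + kcp + kpc2)[close]
    disc[close] <- sqrt(pmax(s^2 - 4 * ke * kpc2, 0))[close]
  }
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  beta[kpc == 0 | ke == 0] <- 0
  list(alpha = alpha, beta = beta)
}
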