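#' Interaction parameters
#'
#' Bundle of the pairwise interaction energies and the base move rate.
#' Energies are in units of \eqn{k_B T} (with \eqn{k_B T \equiv 1}
#' internally) and must be negative (attractive); the strong energy must be
#' deeper than the weak one.  The base rate \eqn{r_0} sets the physical time
#' scale: it is the rate of a translation whose initial and final energies
#' are equal, chosen from the time a free particle needs to diffuse one tile.
#'
#' @param J_s strong pair energy in k_BT, default -2.5.
#' @param J_w weak pair energy in k_BT, default -1.
#' @param r_0 base rate in 1/s, default 2.5e6.
#' @return an object of class `interaction_params`.
#' @examples
#' p <- interaction_params()
#' p$J_s
#' @export
interaction_params <- function(J_s = -2.5, J_w = -1, r_0 = 2.5e6) {
  stopifnot(is.numeric(J_s), is.numeric(J_w), is.numeric(r_0),
            length(J_s) == 1, length(J_w) == 1, length(r_0) == 1)
  if (!(J_s < J_w && J_w < 0))
    stop("invalid interaction energies: need J_s < J_w < 0")
  if (!(r_0 > 0)) stop("r_0 must be positive")
  structure(list(J_s = J_s, J_w = J_w, r_0 = r_0),
            class = "interaction_params")
}

#' @export
print.interaction_params <- function(x, ...) {
  cat(sprintf("interaction parameters: J_s = %g k_BT, J_w = %g k_BT, r_0 = %g 1/s\n",
              x$J_s, x$J_w, x$r_0))
  invisible(x)
}

#' Shocked (drive-reduced) interaction parameters
#'
#' The drive transiently weakens all binding by dividing both interaction
#' energies by the drive amplitude `rho` (a global, pH-like perturbation);
#' the base rate is untouched.  `rho = 1` is the identity (equilibrium).
#'
#' @param params an [interaction_params()] object.
#' @param rho drive amplitude, >= 1.
#' @return an `interaction_params` object with `J_s/rho`, `J_w/rho`.
#' @examples
#' shock_params(interaction_params(J_s = -3.5), rho = 1.5)$J_s  # -2.333...
#' @export
shock_params <- function(params, rho) {
  stopifnot(inherits(params, "interaction_params"),
            is.numeric(rho), length(rho) == 1)
  if (rho < 1) stop("drive amplitude rho must be >= 1")
  interaction_params(J_s = params$J_s / rho, J_w = params$J_w / rho,
                     r_0 = params$r_0)
}
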