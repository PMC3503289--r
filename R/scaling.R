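#' Bead transport properties
#'
#' Radius and effective diffusivities of a spherical hydrogel bead. The
#' defaults describe a 2 mm calcium alginate bead with a substrate
#' (gelatinized starch) effective diffusivity of 7.8e-8 cm^2/min; the
#' product diffusivity defaults to the substrate value (lambda = 1), under
#' which the steady-state sum of the dimensionless substrate and product
#' concentrations is exactly 1.
#'
#' @param R bead radius, cm (default 0.1).
#' @param Ds substrate effective diffusivity, cm^2/min (default 7.8e-8).
#' @param Dp product effective diffusivity, cm^2/min (default \code{Ds}).
#' @return An object of class \code{"bead_transport"}.
#' @export
bead_transport <- function(R = 0.1, Ds = 7.8e-8, Dp = Ds) {
  if (R <= 0) stop("'R' must be positive (cm)")
  if (Ds <= 0) stop("'Ds' must be positive (cm^2/min)")
  if (Dp <= 0) stop("'Dp' must be positive (cm^2/min)")
  structure(list(R = R, Ds = Ds, Dp = Dp), class = "bead_transport")
}

#' @export
print.bead_transport <- function(x, ...) {
  cat(sprintf("Bead transport: R = %g cm, Ds = %g cm^2/min, Dp = %g cm^2/min\n",
              x$R, x$Ds, x$Dp))
  invisible(x)
}

#' Thiele modulus of the bead
#'
#' \code{phi = (R/3) * sqrt(Vmax / (Km * Ds))}, the convention under which
#' the dimensionless reaction source is exactly
#' \code{9 phi^2 Cs / (1 + beta Cs)}. Low phi means reaction-rate control,
#' high phi means internal-diffusion control.
#'
#' @param bt a [bead_transport] (per-minute diffusivity).
#' @param k an [mm_kinetics] (per-minute rates, enforced on construction).
#' @return Thiele modulus (dimensionless).
#' @examples
#' k <- mm_kinetics(Km = 0.34, Vmax = 0.013, rate_unit = "per_sec")
#' thiele_modulus(bead_transport(), k)  # about 180.8
#' @export
thiele_modulus <- function(bt, k) {
  stopifnot(inherits(bt, "bead_transport"), inherits(k, "mm_kinetics"))
  (bt$R / 3) * sqrt(k$Vmax / (k$Km * bt$Ds))
}

#' Saturation parameter
#'
#' \code{beta = S0 / Km}. \code{beta -> 0} gives first-order kinetics,
#' \code{beta >> 1} approaches zero order.
#'
#' @param S0 bulk substrate concentration, g/L (positive).
#' @param Km Michaelis constant, g/L (positive).
#' @return beta (dimensionless).
#' @export
saturation_parameter <- function(S0, Km) {
  if (any(Km <= 0)) stop("'Km' must be positive")
  if (any(S0 <= 0)) stop("'S0' must be positive")
  S0 / Km
}

#' Dimensionless groups of the bead problem
#'
#' Collects the Thiele modulus, saturation parameter, diffusivity ratio
#' \code{lambda = Dp/Ds} and the diffusion time scale \code{R^2/Ds} that
#' nondimensionalize the intraparticle reaction-diffusion equations.
#'
#' @param phi Thiele modulus (nonnegative).
#' @param beta saturation parameter (nonnegative).
#' @param lambda product/substrate diffusivity ratio (positive, default 1).
#' @param tau_scale diffusion time scale \code{R^2/Ds}, min (positive,
#'   default \code{NA} when no dimensional frame is attached).
#' @return An object of class \code{"dimensionless_groups"}.
#' @export
dimensionless_groups <- function(phi, beta, lambda = 1, tau_scale = NA_real_) {
  if (phi < 0) stop("'phi' must be nonnegative")
  if (beta < 0) stop("'beta' must be nonnegative")
  if (lambda <= 0) stop("'lambda' must be positive")
  if (!is.na(tau_scale) && tau_scale <= 0) stop("'tau_scale' must be positive")
  structure(list(phi = phi, beta = beta, lambda = lambda,
                 tau_scale = tau_scale),
            class = "dimensionless_groups")
}

#' @export
print.dimensionless_groups <- function(x, ...) {
  cat(sprintf("Dimensionless groups: phi = %g, beta = %g, lambda = %g",
              x$phi, x$beta, x$lambda))
  if (!is.na(x$tau_scale)) cat(sprintf(", R^2/Ds = %g min", x$tau_scale))
  cat("\n")
  invisible(x)
}

#' Derive the dimensionless groups from lab-frame parameters
#'
#' @param bt a [bead_transport].
#' @param k an [mm_kinetics].
#' @param S0 bulk substrate concentration, g/L.
#' @return A [dimensionless_groups] object with
#'   \code{phi = (R/3) sqrt(Vmax/(Km Ds))}, \code{beta = S0/Km},
#'   \code{lambda = Dp/Ds} and \code{tau_scale = R^2/Ds}.
#' @export
scale_parameters <- function(bt, k, S0) {
  dimensionless_groups(phi = thiele_modulus(bt, k),
                       beta = saturation_parameter(S0, k$Km),
                       lambda = bt$Dp / bt$Ds,
                       tau_scale = bt$R^2 / bt$Ds)
}

#' Nondimensionalize lab-frame quantities
#'
#' \code{Cs = S/S0}, \code{Cp = P/S0}, \code{tau = t Ds / R^2},
#' \code{r_dot = r/R}, \code{z_dot = z/R}. [redimensionalize] is the exact
#' inverse.
#'
#' @param S,P substrate and product concentrations, g/L.
#' @param t time, min.
#' @param r,z cylindrical coordinates, cm.
#' @param S0 bulk substrate concentration, g/L (positive).
#' @param bt a [bead_transport].
#' @return A list with \code{Cs}, \code{Cp}, \code{tau}, \code{r_dot},
#'   \code{z_dot}.
#' @export
nondimensionalize <- function(S, P, t, r, z, S0, bt) {
  stopifnot(inherits(bt, "bead_transport"))
  if (S0 <= 0) stop("'S0' must be positive")
  list(Cs = S / S0, Cp = P / S0, tau = t * bt$Ds / bt$R^2,
       r_dot = r / bt$R, z_dot = z / bt$R)
}

#' Map dimensionless quantities back to the lab frame
#'
#' @param Cs,Cp dimensionless substrate and product concentrations.
#' @param tau dimensionless time.
#' @param r_dot,z_dot dimensionless coordinates.
#' @param S0 bulk substrate concentration, g/L.
#' @param bt a [bead_transport].
#' @return A list with \code{S}, \code{P} (g/L), \code{t} (min), \code{r},
#'   \code{z} (cm).
#' @export
redimensionalize <- function(Cs, Cp, tau, r_dot, z_dot, S0, bt) {
  stopifnot(inherits(bt, "bead_transport"))
  if (S0 <= 0) stop("'S0' must be positive")
  list(S = Cs * S0, P = Cp * S0, t = tau * bt$R^2 / bt$Ds,
       r = r_dot * bt$R, z = z_dot * bt$R)
}
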