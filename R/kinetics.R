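#' Michaelis-Menten kinetic parameter set
#'
#' Bundles the Michaelis constant \code{Km} and maximal volumetric rate
#' \code{Vmax} of an enzyme, optionally together with the turnover number
#' \code{k2}, the enzyme load \code{E0}, and the elementary rate constants
#' \code{k1}, \code{k_minus1}. The internal unit system is fixed to
#' g, L and minutes; rates supplied per second (the common way starch
#' hydrolysis activities are tabulated) are converted on ingestion via
#' \code{rate_unit = "per_sec"}.
#'
#' If both \code{k2} and \code{E0} are given they must satisfy
#' \code{Vmax = k2 * E0}; if \code{k1}, \code{k_minus1} and \code{k2} are
#' all given they must satisfy \code{Km = (k_minus1 + k2) / k1}. The
#' elementary constants are carried as metadata only: \code{Km} and
#' \code{Vmax} do not identify them separately.
#'
#' @param Km Michaelis constant, g/L. Must be positive.
#' @param Vmax maximal volumetric rate, g/(L.min) (or g/(L.s) with
#'   \code{rate_unit = "per_sec"}). Must be positive.
#' @param k2 optional turnover number, 1/min (or 1/s per \code{rate_unit}).
#' @param E0 optional enzyme load, g/L.
#' @param k1,k_minus1 optional elementary rate constants (informational).
#' @param rate_unit time base of the supplied rates: \code{"per_min"}
#'   (default, internal) or \code{"per_sec"} (multiplied by 60 on ingestion).
#'
#' @return An object of class \code{"mm_kinetics"}: a list with elements
#'   \code{Km}, \code{Vmax} (g/(L.min)) and any optional constants, all on
#'   the per-minute base.
#' @examples
#' k <- mm_kinetics(Km = 3.38, Vmax = 0.134, rate_unit = "per_sec")
#' k$Vmax  # 8.04 g/(L.min)
#' @export
mm_kinetics <- function(Km, Vmax, k2 = NULL, E0 = NULL,
                        k1 = NULL, k_minus1 = NULL,
                        rate_unit = c("per_min", "per_sec")) {
  rate_unit <- match.arg(rate_unit)
  fac <- if (rate_unit == "per_sec") 60 else 1
  stopifnot(is.numeric(Km), length(Km) == 1L, is.finite(Km),
            is.numeric(Vmax), length(Vmax) == 1L, is.finite(Vmax))
  if (Km <= 0) stop("'Km' must be positive (g/L)")
  if (Vmax <= 0) stop("'Vmax' must be positive")
  Vmax <- Vmax * fac
  if (!is.null(k2)) {
    if (k2 <= 0) stop("'k2' must be positive")
    k2 <- k2 * fac
  }
  if (!is.null(E0) && E0 <= 0) stop("'E0' must be positive (g/L)")
  if (!is.null(k2) && !is.null(E0) &&
      abs(Vmax - k2 * E0) / Vmax >= 1e-9)
    stop("inconsistent parameters: Vmax must equal k2 * E0")
  if (!is.null(k1) && !is.null(k_minus1) && !is.null(k2)) {
    if (k1 <= 0) stop("'k1' must be positive")
    if (k_minus1 < 0) stop("'k_minus1' must be nonnegative")
    if (abs(Km - (k_minus1 * fac + k2) / (k1 * fac)) / Km >= 1e-9)
      stop("inconsistent parameters: Km must equal (k_minus1 + k2) / k1")
  }
  structure(
    list(Km = Km, Vmax = Vmax, k2 = k2, E0 = E0,
         k1 = if (is.null(k1)) NULL else k1 * fac,
         k_minus1 = if (is.null(k_minus1)) NULL else k_minus1 * fac),
    class = "mm_kinetics")
}

#' @export
print.mm_kinetics <- function(x, ...) {
  cat("Michaelis-Menten kinetics\n")
  cat(sprintf("  Km   = %g g/L\n", x$Km))
  cat(sprintf("  Vmax = %g g/(L.min)\n", x$Vmax))
  if (!is.null(x$k2)) cat(sprintf("  k2   = %g 1/min\n", x$k2))
  if (!is.null(x$E0)) cat(sprintf("  E0   = %g g/L\n", x$E0))
  invisible(x)
}

#' Michaelis-Menten rate law
#'
#' Volumetric reaction rate \code{v = Vmax * S / (Km + S)} at substrate
#' concentration \code{S}. The rate is monotone nondecreasing in \code{S}
#' and bounded above by \code{Vmax}.
#'
#' @param S substrate concentration, g/L (vectorized). Must be nonnegative.
#' @param k an [mm_kinetics] object.
#' @return Reaction rate(s), g/(L.min).
#' @examples
#' k <- mm_kinetics(Km = 1, Vmax = 2)
#' mm_rate(1, k)      # Vmax/2 at half-saturation
#' @export
mm_rate <- function(S, k) {
  stopifnot(inherits(k, "mm_kinetics"))
  if (any(S < 0)) stop("substrate concentration 'S' must be nonnegative")
  k$Vmax * S / (k$Km + S)
}

#' Integrated Michaelis-Menten reaction time
#'
#' Time needed to take the substrate from \code{S0} down to \code{St} under
#' Michaelis-Menten kinetics in a plug-flow / batch frame:
#' \code{t = (Km * log(S0/St) + (S0 - St)) / Vmax}. Strictly decreasing in
#' \code{St}, zero at \code{St = S0}.
#'
#' @param S0 inlet (initial) substrate concentration, g/L.
#' @param St outlet substrate concentration, g/L, in \code{(0, S0]}.
#' @param k an [mm_kinetics] object.
#' @return Time in minutes.
#' @examples
#' integrated_time(2, 1, mm_kinetics(Km = 1, Vmax = 1))  # log(2) + 1
#' @export
integrated_time <- function(S0, St, k) {
  stopifnot(inherits(k, "mm_kinetics"))
  if (any(S0 <= 0)) stop("'S0' must be positive")
  if (any(St <= 0)) stop("'St' must be positive: the logarithmic term diverges at zero")
  if (any(St > S0)) stop("'St' must not exceed 'S0'")
  (k$Km * log(S0 / St) + (S0 - St)) / k$Vmax
}

#' Predict the outlet substrate concentration
#'
#' Inverts the integrated Michaelis-Menten relation: finds the unique
#' \code{St} in \code{(0, S0]} with
#' \code{Km * log(S0/St) + (S0 - St) = Vmax * t}. The root is found in the
#' log-concentration variable \code{u = log(St/S0)}, where the residual
#' \code{g(u) = -Km u + S0 (1 - exp(u)) - Vmax t} is strictly decreasing
#' and brackets analytically in \code{[-Vmax t / Km, 0]}; working in
#' \code{u} keeps full relative precision even at deep conversion, where
#' \code{St} is many orders of magnitude below \code{S0}. The bracketed
#' root is polished by two Newton steps.
#'
#' @param S0 inlet substrate concentration, g/L.
#' @param t residence (reaction) time, min (vectorized). Must be >= 0.
#' @param k an [mm_kinetics] object.
#' @return Outlet concentration(s) \code{St}, g/L.
#' @examples
#' k <- mm_kinetics(Km = 1, Vmax = 1)
#' predict_outlet(2, log(2) + 1, k)  # 1
#' @export
predict_outlet <- function(S0, t, k) {
  stopifnot(inherits(k, "mm_kinetics"))
  if (S0 <= 0) stop("'S0' must be positive")
  if (any(t < 0)) stop("time 't' must be nonnegative")
  vapply(t, function(ti) {
    if (ti == 0) return(S0)
    g <- function(u) -k$Km * u + S0 * (1 - exp(u)) - k$Vmax * ti
    u_lo <- -k$Vmax * ti / k$Km         # g(u_lo) = S0 (1 - exp(u_lo)) >= 0
    r <- stats::uniroot(g, c(u_lo, 0), tol = 1e-12, maxiter = 1000L)
    u <- r$root
    for (i in 1:2) u <- u - g(u) / (-k$Km - S0 * exp(u))  # Newton polish
    S0 * exp(u)
  }, numeric(1))
}

#' Fractional substrate conversion
#'
#' \code{X = (S0 - St) / S0}, in \code{[0, 1]}.
#'
#' @param S0 inlet substrate concentration, g/L (positive).
#' @param St outlet substrate concentration, g/L, in \code{[0, S0]}.
#' @return Conversion(s) in \code{[0, 1]}.
#' @export
conversion <- function(S0, St) {
  if (any(S0 <= 0)) stop("'S0' must be positive")
  if (any(St < 0)) stop("'St' must be nonnegative")
  if (any(St > S0)) stop("'St' must not exceed 'S0'")
  (S0 - St) / S0
}

#' Turnover number from Vmax and enzyme load
#'
#' \code{k2 = Vmax / E0}: substrate mass converted per unit enzyme mass per
#' unit time at saturation.
#'
#' @param Vmax maximal volumetric rate, g/(L.min).
#' @param E0 enzyme load, g/L (positive).
#' @return Turnover number, 1/min.
#' @export
turnover_number <- function(Vmax, E0) {
  if (any(E0 <= 0)) stop("'E0' must be positive")
  Vmax / E0
}

#' Conversion-experiment series
#'
#' One fixed-bed experiment: a single inlet concentration \code{S0} and an
#' ordered set of (residence time, outlet concentration) observations.
#'
#' @param S0 inlet substrate concentration, g/L (positive scalar).
#' @param t residence times, min; strictly positive and strictly increasing.
#' @param St outlet concentrations, g/L; each in \code{[0, S0]}.
#' @return An object of class \code{"conversion_series"}: a list with
#'   \code{S0} and a data frame \code{observations} (columns \code{t},
#'   \code{St}).
#' @export
conversion_series <- function(S0, t, St) {
  stopifnot(length(S0) == 1L, length(t) == length(St))
  if (S0 <= 0) stop("'S0' must be positive")
  if (any(t <= 0)) stop("residence times must be strictly positive")
  if (any(diff(t) <= 0)) stop("residence times must be strictly increasing")
  if (any(St < 0)) stop("outlet concentrations must be nonnegative")
  if (any(St > S0)) stop("outlet concentrations must not exceed 'S0'")
  structure(list(S0 = S0,
                 observations = data.frame(t = as.numeric(t),
                                           St = as.numeric(St))),
            class = "conversion_series")
}

#' @export
print.conversion_series <- function(x, ...) {
  cat(sprintf("Conversion series: S0 = %g g/L, %d observations, t in [%g, %g] min\n",
              x$S0, nrow(x$observations),
              min(x$observations$t), max(x$observations$t)))
  invisible(x)
}
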