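#' Fixed-bed reactor specification
#'
#' @param VR reactor volume, cm^3 (positive).
#' @param epsilon bed void fraction, strictly between 0 and 1.
#' @param Q volumetric feed flow rate, mL/min (positive).
#' @param Vb optional total bead volume, cm^3.
#' @return An object of class \code{"reactor_spec"}.
#' @export
reactor_spec <- function(VR, epsilon, Q, Vb = NULL) {
  if (VR <= 0) stop("'VR' must be positive (cm^3)")
  if (epsilon <= 0 || epsilon >= 1) stop("'epsilon' must lie strictly in (0, 1)")
  if (Q <= 0) stop("'Q' must be positive (mL/min)")
  if (!is.null(Vb) && Vb <= 0) stop("'Vb' must be positive (cm^3)")
  structure(list(VR = VR, epsilon = epsilon, Q = Q, Vb = Vb),
            class = "reactor_spec")
}

#' @export
print.reactor_spec <- function(x, ...) {
  cat(sprintf("Fixed-bed reactor: VR = %g cm^3, voidage = %g, Q = %g mL/min\n",
              x$VR, x$epsilon, x$Q))
  invisible(x)
}

#' Mean residence time of the liquid in the bed
#'
#' \code{t = epsilon * VR / Q}: interstitial liquid volume over flow rate.
#' Linear in \code{VR} and \code{epsilon}, antitone in \code{Q}.
#'
#' @param spec a [reactor_spec].
#' @return Residence time, min.
#' @examples
#' residence_time(reactor_spec(VR = 60, epsilon = 0.42, Q = 5.04))  # 5 min
#' @export
residence_time <- function(spec) {
  stopifnot(inherits(spec, "reactor_spec"))
  spec$epsilon * spec$VR / spec$Q
}

#' Bed void fraction from the liquid-impregnation measurement
#'
#' @param void_volume liquid volume filling the interstices, cm^3.
#' @param reactor_volume total bed volume, cm^3 (positive).
#' @return Void fraction in \code{[0, 1]}.
#' @export
void_fraction <- function(void_volume, reactor_volume) {
  if (reactor_volume <= 0) stop("'reactor_volume' must be positive")
  if (void_volume < 0) stop("'void_volume' must be nonnegative")
  if (void_volume > reactor_volume)
    stop("'void_volume' cannot exceed 'reactor_volume'")
  void_volume / reactor_volume
}

#' Enzyme entrapment efficiency
#'
#' Percentage of the loaded enzyme retained in the beads:
#' \code{100 * (C_en - C_un) / C_en}, with \code{C_en} the enzyme amount
#' loaded and \code{C_un} the unentrapped amount found in the outlet.
#'
#' @param C_en loaded enzyme concentration, g/L (positive).
#' @param C_un unentrapped enzyme concentration, g/L, in \code{[0, C_en]}.
#' @return Efficiency in percent.
#' @export
entrapment_efficiency <- function(C_en, C_un) {
  if (any(C_en <= 0)) stop("'C_en' must be positive")
  if (any(C_un < 0)) stop("'C_un' must be nonnegative")
  if (any(C_un > C_en)) stop("'C_un' cannot exceed 'C_en'")
  100 * (C_en - C_un) / C_en
}

#' Linearize a conversion series for Michaelis-Menten estimation
#'
#' Maps each observation to the coordinates of the integrated-rate
#' linearization: \code{x = X/t} against \code{y = log(1 - X)/t}, where
#' \code{X} is the fractional conversion. Data generated exactly by the
#' integrated rate law fall on one straight line
#' \code{y = (S0/Km) x - Vmax/Km}, i.e. slope \code{S0/Km} and intercept
#' \code{-Vmax/Km}.
#'
#' Observations at (numerically) complete conversion have an undefined
#' logarithm; they abort with an error unless \code{drop_complete = TRUE},
#' which excludes them with a warning. They are never clipped: clipping
#' would bias the slope.
#'
#' @param series a [conversion_series].
#' @param drop_complete drop observations with \code{X >= 1 - 1e-12}
#'   instead of erroring.
#' @return A data frame with columns \code{x} (\code{X/t}, 1/min) and
#'   \code{y} (\code{log(1-X)/t}, 1/min), one row per retained observation.
#' @export
linearize_conversion <- function(series, drop_complete = FALSE) {
  stopifnot(inherits(series, "conversion_series"))
  obs <- series$observations
  X <- conversion(series$S0, obs$St)
  complete <- obs$St / series$S0 <= 1e-12      # X >= 1 - 1e-12
  if (any(complete)) {
    if (!drop_complete)
      stop("complete conversion (X = 1) observed: log(1 - X) is undefined; ",
           "set drop_complete = TRUE to exclude these points")
    warning(sprintf("dropping %d observation(s) at complete conversion",
                    sum(complete)))
    obs <- obs[!complete, , drop = FALSE]
    X <- X[!complete]
  }
  # log(1 - X) evaluated as log(St/S0): identical algebraically, but free
  # of the catastrophic cancellation 1 - X suffers at deep conversion
  data.frame(x = X / obs$t, y = log(obs$St / series$S0) / obs$t)
}

#' Estimate Km and Vmax from fixed-bed conversion data
#'
#' Ordinary least squares of \code{log(1-X)/t} on \code{X/t} (see
#' [linearize_conversion]); the fitted line has slope \code{S0/Km} and
#' intercept \code{-Vmax/Km}, so \code{Km_hat = S0/slope} and
#' \code{Vmax_hat = -intercept * Km_hat}. No weighting is applied,
#' matching the graphical method the linearization was designed for.
#'
#' @param series a [conversion_series].
#' @param drop_complete passed to [linearize_conversion].
#' @return An object of class \code{"mm_fit"}: list with \code{slope},
#'   \code{intercept} (1/min), \code{Km_hat} (g/L), \code{Vmax_hat}
#'   (g/(L.min)), \code{r_squared}, \code{n_points} and \code{S0}.
#' @examples
#' k <- mm_kinetics(Km = 2, Vmax = 0.5)
#' tt <- c(5, 10, 20, 40)
#' ser <- conversion_series(10, tt, predict_outlet(10, tt, k))
#' estimate_km_vmax(ser)
#' @export
estimate_km_vmax <- function(series, drop_complete = FALSE) {
  pts <- linearize_conversion(series, drop_complete = drop_complete)
  if (nrow(pts) < 2L || length(unique(pts$x)) < 2L)
    stop("need at least 2 observations with distinct X/t to fit the line")
  fit <- stats::lm(y ~ x, data = pts)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  if (slope <= 0)
    stop(sprintf(paste0("estimation failure: nonpositive slope (%g) would give",
                        " a nonpositive Km"), slope))
  Km_hat <- series$S0 / slope
  Vmax_hat <- -intercept * Km_hat
  r2 <- if (nrow(pts) == 2L) 1 else summary(fit)$r.squared
  structure(list(slope = slope, intercept = intercept,
                 Km_hat = Km_hat, Vmax_hat = Vmax_hat,
                 r_squared = r2, n_points = nrow(pts), S0 = series$S0),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("Integrated-rate linearized fit\n")
  cat(sprintf("  S0       = %g g/L (%d points)\n", x$S0, x$n_points))
  cat(sprintf("  Km_hat   = %g g/L\n", x$Km_hat))
  cat(sprintf("  Vmax_hat = %g g/(L.min)\n", x$Vmax_hat))
  cat(sprintf("  R^2      = %.6f\n", x$r_squared))
  invisible(x)
}
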