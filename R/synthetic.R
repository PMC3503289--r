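#' Scenario specification for synthetic conversion experiments
#'
#' Defines the design of a simulated fixed-bed conversion study: the true
#' kinetics, the grids of inlet concentrations and residence times, the
#' measurement-noise level and the random seed. The default grids span the
#' operating window of a bench-scale packed column of alginate-entrapped
#' amylase: inlet starch 1-100 g/L, residence times 5-120 min.
#'
#' @param true_kinetics an [mm_kinetics]: the generating parameters.
#' @param S0_grid inlet concentrations, g/L (positive).
#' @param t_grid residence times, min (positive, increasing).
#' @param noise_cv coefficient of variation of the multiplicative
#'   measurement noise on the outlet concentration (>= 0; 0 = exact data).
#' @param seed integer random seed.
#' @param replicates datasets per inlet concentration (>= 1).
#' @return An object of class \code{"scenario_spec"}.
#' @export
scenario_spec <- function(true_kinetics,
                          S0_grid = c(1, 5, 10, 50, 100),
                          t_grid = c(5, 10, 20, 40, 60, 90, 120),
                          noise_cv = 0, seed = 20121031L, replicates = 1L) {
  stopifnot(inherits(true_kinetics, "mm_kinetics"))
  if (length(S0_grid) == 0 || any(S0_grid <= 0))
    stop("'S0_grid' must be nonempty and strictly positive")
  if (length(t_grid) == 0 || any(t_grid <= 0))
    stop("'t_grid' must be nonempty and strictly positive")
  if (any(diff(t_grid) <= 0)) stop("'t_grid' must be strictly increasing")
  if (noise_cv < 0) stop("'noise_cv' must be nonnegative")
  if (replicates < 1) stop("'replicates' must be at least 1")
  structure(list(true_kinetics = true_kinetics,
                 S0_grid = as.numeric(S0_grid),
                 t_grid = as.numeric(t_grid),
                 noise_cv = noise_cv, seed = as.integer(seed),
                 replicates = as.integer(replicates)),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Synthetic conversion scenario: %d inlet levels x %d times x %d replicate(s), noise CV = %g, seed = %d\n",
              length(x$S0_grid), length(x$t_grid), x$replicates,
              x$noise_cv, x$seed))
  invisible(x)
}

#' Generate synthetic fixed-bed conversion series
#'
#' For each inlet concentration and replicate, the exact outlet
#' concentration is computed from the integrated Michaelis-Menten law
#' ([predict_outlet]) and then perturbed by mean-one multiplicative
#' lognormal noise: \code{St_obs = St_true * exp(z)} with
#' \code{z ~ N(-sigma^2/2, sigma^2)}, \code{sigma^2 = log(1 + cv^2)}, so
#' the expectation of the observation equals the noiseless value. Results
#' are clipped into \code{(0, S0]}. Identical seeds give identical output;
#' \code{noise_cv = 0} returns exact integrated-rate data.
#'
#' @param spec a [scenario_spec].
#' @return A list of [conversion_series], one per (S0, replicate), in
#'   S0-major order; each carries attributes \code{S0} and \code{replicate}.
#' @export
generate_series <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  k <- spec$true_kinetics
  sigma2 <- log(1 + spec$noise_cv^2)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  out <- list()
  for (S0 in spec$S0_grid) {
    St_true <- predict_outlet(S0, spec$t_grid, k)
    for (rep in seq_len(spec$replicates)) {
      St <- St_true
      if (spec$noise_cv > 0) {
        z <- stats::rnorm(length(St), mean = -sigma2 / 2, sd = sqrt(sigma2))
        St <- pmin(pmax(St * exp(z), S0 * 1e-12), S0)
      }
      ser <- conversion_series(S0, spec$t_grid, St)
      attr(ser, "replicate") <- rep
      out[[length(out) + 1L]] <- ser
    }
  }
  out
}

#' Default scenario echoing the bench-scale starch-hydrolysis design
#'
#' Inlet-concentration grid 1, 5, 10, 50, 100 g/L; residence-time grid 5,
#' 10, 20, 40, 60, 90, 120 min; generating kinetics Km = 3.38 g/L and
#' Vmax = 0.134 g/(L.s) (converted to the per-minute internal base), a
#' parameter pair representative of immobilized fungal amylase on
#' gelatinized corn starch at 50 C and pH 5.5.
#'
#' @param noise_cv measurement-noise coefficient of variation (default 0).
#' @param replicates datasets per inlet level (default 1).
#' @param seed random seed (default 20121031).
#' @return A [scenario_spec].
#' @export
scenario_starch_default <- function(noise_cv = 0, replicates = 1L,
                                    seed = 20121031L) {
  scenario_spec(mm_kinetics(Km = 3.38, Vmax = 0.134, rate_unit = "per_sec"),
                noise_cv = noise_cv, replicates = replicates, seed = seed)
}
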