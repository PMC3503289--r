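#' @importFrom Matrix Diagonal solve t
NULL

# Shared nonlinear driver for the steady problem
#   L C + b_unit - 9 phi^2 C / (1 + beta C) = 0,  surface value 1.
# Picard with under-relaxation (the Michaelis-Menten denominator is frozen
# at the previous iterate, leaving a linear M-matrix system), falling back
# to damped Newton if Picard stalls. The linearized systems keep the
# M-matrix structure, so iterates respect 0 <= C <= 1 (discrete maximum
# principle).
solve_steady_core <- function(L, b_unit, phi, beta, tol = 1e-10,
                              max_picard = 500L, relax = 0.8) {
  N <- length(b_unit)
  s2 <- 9 * phi^2
  resid <- function(C) {
    as.numeric(L %*% C) + b_unit - s2 * C / (1 + beta * C)
  }
  # roundoff floor: residual entries carry O(eps * coefficient magnitude)
  tol_eff <- max(tol, 1e-14 * (s2 + max(abs(L@x))))
  if (s2 == 0) {                        # pure diffusion: C = 1 exactly
    C <- rep(1, N)
    return(list(C = C, converged = TRUE, residual = max(abs(resid(C))),
                iterations = 0L, method = "exact"))
  }
  C <- rep(0, N)
  r <- max(abs(resid(C)))
  it <- 0L
  while (r > tol_eff && it < max_picard) {
    A <- -L + Matrix::Diagonal(N, x = s2 / (1 + beta * C))
    Cnew <- as.numeric(Matrix::solve(A, b_unit))
    C <- relax * Cnew + (1 - relax) * C
    r <- max(abs(resid(C)))
    it <- it + 1L
  }
  method <- "picard"
  if (r > tol_eff) {                    # damped Newton fallback
    method <- "newton"
    for (nit in 1:100) {
      F <- resid(C)
      r <- max(abs(F))
      if (r <= tol_eff) break
      J <- L - Matrix::Diagonal(N, x = s2 / (1 + beta * C)^2)
      delta <- as.numeric(Matrix::solve(J, -F))
      step <- 1
      repeat {
        Ctry <- C + step * delta
        if (max(abs(resid(Ctry))) < r || step < 1e-6) break
        step <- step / 2
      }
      C <- Ctry
      it <- it + 1L
    }
    r <- max(abs(resid(C)))
  }
  if (r > tol_eff)
    stop(sprintf("steady solve did not converge: residual %.3e after %d iterations (phi = %g, beta = %g)",
                 r, it, phi, beta))
  list(C = C, converged = TRUE, residual = r, iterations = it,
       method = method)
}

new_bead_field <- function(type, mesh, Cs, Cp, groups, converged,
                           residual_norm, tau = NA_real_) {
  structure(list(type = type, mesh = mesh, Cs = Cs, Cp = Cp,
                 groups = groups, converged = converged,
                 residual_norm = residual_norm, tau = tau),
            class = "bead_field")
}

#' @export
print.bead_field <- function(x, ...) {
  cat(sprintf("Bead %s field: phi = %g, beta = %g%s\n", x$type,
              x$groups$phi, x$groups$beta,
              if (is.na(x$tau)) " (steady)" else sprintf(" at tau = %g", x$tau)))
  cc <- center_concentration(x)
  cat(sprintf("  Cs range [%.4g, %.4g], centre Cs = %.4g, residual = %.2e\n",
              min(x$Cs), max(x$Cs), cc, x$residual_norm))
  invisible(x)
}

#' Steady substrate profile in a sphere (radial problem)
#'
#' Solves the radially symmetric steady reaction-diffusion balance
#' \deqn{\frac{1}{\rho^2}\frac{d}{d\rho}\Big(\rho^2\frac{dC}{d\rho}\Big)
#'   = \frac{9\phi^2 C}{1+\beta C}}
#' with \code{C(1) = 1} and zero gradient at the centre, on a uniform node
#' grid by conservative second-order finite differences. The nonlinearity
#' is handled by under-relaxed Picard iteration with a damped-Newton
#' fallback.
#'
#' @param phi Thiele modulus (>= 0).
#' @param beta saturation parameter (>= 0).
#' @param n_radial number of radial intervals (>= 16).
#' @param lambda diffusivity ratio stored with the field (default 1).
#' @param tol residual (discrete max-norm) convergence tolerance.
#' @return A \code{"bead_field"} of type \code{"radial"}: \code{Cs} on the
#'   nodes \code{rho = 0, 1/n, ..., 1} (surface value 1 included), the
#'   steady product profile \code{Cp = (1 - Cs)/lambda} implied by the
#'   summed-species balance, plus convergence diagnostics.
#' @examples
#' f <- steady_sphere_1d(phi = 1, beta = 0, n_radial = 64)
#' profile_at(f, 0.5)   # about sinh(1.5) / (0.5 * sinh(3))
#' @export
steady_sphere_1d <- function(phi, beta, n_radial = 64, lambda = 1,
                             tol = 1e-10) {
  if (phi < 0 || beta < 0) stop("'phi' and 'beta' must be nonnegative")
  if (n_radial < 16) stop("mesh too coarse: 'n_radial' must be at least 16")
  op <- radial_operator(n_radial)
  sol <- solve_steady_core(op$L, op$b_unit, phi, beta, tol = tol)
  Cs <- c(sol$C, 1)
  # steady state with surface values Cs = 1, Cp = 0: Ds(1 - Cs) = Dp Cp
  Cp <- (1 - Cs) / lambda
  mesh <- list(rho = c(op$rho, 1), h = op$h, n = n_radial)
  new_bead_field("radial", mesh, Cs, Cp,
                 dimensionless_groups(phi, beta, lambda),
                 sol$converged, sol$residual)
}

#' Steady substrate field on the axisymmetric quarter cross-section
#'
#' Solves the steady dimensionless substrate balance
#' \deqn{\frac{1}{\dot r}\frac{\partial}{\partial \dot r}\Big(\dot r
#'   \frac{\partial C_s}{\partial \dot r}\Big)
#'   + \frac{\partial^2 C_s}{\partial \dot z^2}
#'   = \frac{9\phi^2 C_s}{1+\beta C_s}}
#' on the quarter cross-section of the bead, with \code{Cs = 1} on the
#' spherical surface and zero normal derivative on the symmetry axis and
#' the midplane. The domain is handled on the spherical-polar mapped grid
#' of [axi_mesh]; see that help page for the boundary treatment.
#'
#' @param phi Thiele modulus (>= 0).
#' @param beta saturation parameter (>= 0).
#' @param mesh an [axi_mesh] (or an integer, taken as the resolution of a
#'   new mesh).
#' @param lambda diffusivity ratio stored with the field (default 1).
#' @param tol residual convergence tolerance.
#' @return A \code{"bead_field"} of type \code{"axisymmetric"}: \code{Cs}
#'   and \code{Cp} as n x m matrices on the cell centres.
#' @export
steady_axisymmetric <- function(phi, beta, mesh, lambda = 1, tol = 1e-10) {
  if (phi < 0 || beta < 0) stop("'phi' and 'beta' must be nonnegative")
  if (is.numeric(mesh)) mesh <- axi_mesh(mesh)
  stopifnot(inherits(mesh, "axi_mesh"))
  op <- axi_operator(mesh)
  sol <- solve_steady_core(op$L, op$b_unit, phi, beta, tol = tol)
  Cs <- matrix(sol$C, mesh$n, mesh$m)
  Cp <- (1 - Cs) / lambda
  new_bead_field("axisymmetric", mesh, Cs, Cp,
                 dimensionless_groups(phi, beta, lambda),
                 sol$converged, sol$residual)
}

#' Transient substrate and product fields in the bead
#'
#' Integrates the coupled dimensionless balances
#' \deqn{\partial C_s/\partial\tau = \nabla^2 C_s - 9\phi^2 C_s/(1+\beta C_s)}
#' \deqn{\partial C_p/\partial\tau = \lambda \nabla^2 C_p + 9\phi^2 C_s/(1+\beta C_s)}
#' from an initially empty bead (\code{Cs = Cp = 0}) suddenly exposed to
#' bulk liquid (\code{Cs = 1}, \code{Cp = 0} on the surface), by the method
#' of lines on the [axi_mesh] discretization with a stiff sparse BDF
#' integrator (\code{deSolve::lsodes}). At \code{lambda = 1} the summed
#' species \code{W = Cs + Cp} obeys a pure diffusion equation with unit
#' boundary value, so \code{W -> 1} uniformly as \code{tau} grows.
#'
#' @param phi Thiele modulus (>= 0).
#' @param beta saturation parameter (>= 0).
#' @param lambda product/substrate diffusivity ratio (> 0).
#' @param tau_end final dimensionless time (> 0).
#' @param mesh an [axi_mesh] (or an integer resolution).
#' @param n_snapshots number of output snapshots, equally spaced in
#'   \code{(0, tau_end]}; the initial state is always included.
#' @param rtol,atol integrator tolerances.
#' @return A list of class \code{"bead_transient"}: \code{tau} (snapshot
#'   times) and \code{fields}, a list of \code{"bead_field"} objects.
#' @export
transient_solve <- function(phi, beta, lambda = 1, tau_end = 1, mesh = 24,
                            n_snapshots = 10, rtol = 1e-8, atol = 1e-10) {
  if (phi < 0 || beta < 0) stop("'phi' and 'beta' must be nonnegative")
  if (lambda <= 0) stop("'lambda' must be positive")
  if (tau_end <= 0) stop("'tau_end' must be positive")
  if (is.numeric(mesh)) mesh <- axi_mesh(mesh)
  stopifnot(inherits(mesh, "axi_mesh"))
  op <- axi_operator(mesh)
  N <- mesh$n * mesh$m
  s2 <- 9 * phi^2
  deriv <- function(t, y, parms) {
    Cs <- y[1:N]; Cp <- y[(N + 1):(2 * N)]
    rate <- s2 * Cs / (1 + beta * Cs)
    dCs <- as.numeric(op$L %*% Cs) + op$b_unit - rate
    dCp <- lambda * as.numeric(op$L %*% Cp) + rate   # Cp surface value 0
    list(c(dCs, dCp))
  }
  taus <- c(0, seq(tau_end / n_snapshots, tau_end, length.out = n_snapshots))
  out <- deSolve::ode(y = rep(0, 2 * N), times = taus, func = deriv,
                      parms = NULL, method = "lsodes",
                      rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop(sprintf("transient integration failed near tau = %g",
                 max(out[, 1])))
  fields <- lapply(seq_len(nrow(out)), function(r) {
    y <- out[r, -1]
    new_bead_field("axisymmetric", mesh,
                   matrix(y[1:N], mesh$n, mesh$m),
                   matrix(y[(N + 1):(2 * N)], mesh$n, mesh$m),
                   dimensionless_groups(phi, beta, lambda),
                   converged = TRUE, residual_norm = NA_real_,
                   tau = out[r, 1])
  })
  structure(list(tau = out[, 1], fields = fields,
                 phi = phi, beta = beta, lambda = lambda),
            class = "bead_transient")
}

#' @export
print.bead_transient <- function(x, ...) {
  cat(sprintf("Transient bead solution: phi = %g, beta = %g, lambda = %g, %d snapshots to tau = %g\n",
              x$phi, x$beta, x$lambda, length(x$tau), max(x$tau)))
  invisible(x)
}

#' Radial substrate profile of a bead field
#'
#' For a radial field, returns the nodal profile directly. For an
#' axisymmetric field the solution of the uniform-surface problem is
#' radially symmetric, so cell values are averaged over the polar angle at
#' each radius.
#'
#' @param field a \code{"bead_field"}.
#' @param species \code{"Cs"} (default) or \code{"Cp"}.
#' @return A data frame with columns \code{rho} and the species value.
#' @export
field_profile <- function(field, species = c("Cs", "Cp")) {
  stopifnot(inherits(field, "bead_field"))
  species <- match.arg(species)
  v <- field[[species]]
  if (field$type == "radial") {
    out <- data.frame(rho = field$mesh$rho, value = v)
  } else {
    out <- data.frame(rho = field$mesh$rho, value = rowMeans(v))
  }
  names(out)[2] <- species
  out
}

#' Interpolate a field's substrate profile at given radii
#'
#' Natural cubic spline through the radial profile (with the surface value
#' 1 appended for steady axisymmetric fields).
#'
#' @param field a \code{"bead_field"}.
#' @param rho radii in \code{[0, 1]}.
#' @param species \code{"Cs"} or \code{"Cp"}.
#' @return Interpolated values at \code{rho}.
#' @export
profile_at <- function(field, rho, species = c("Cs", "Cp")) {
  species <- match.arg(species)
  pr <- field_profile(field, species)
  x <- pr$rho; y <- pr[[species]]
  if (field$type == "axisymmetric" && is.na(field$tau)) {
    # steady surface values are known exactly
    x <- c(x, 1); y <- c(y, if (species == "Cs") 1 else 0)
  }
  stats::spline(x, y, xout = rho, method = "natural")$y
}

#' Substrate concentration at the bead centre
#'
#' Radial fields carry the centre node directly; for cell-centred
#' axisymmetric fields the even symmetry of the profile is used to
#' extrapolate quadratically from the two innermost radii.
#'
#' @param field a \code{"bead_field"}.
#' @return Dimensionless centre concentration.
#' @export
center_concentration <- function(field) {
  pr <- field_profile(field, "Cs")
  if (field$type == "radial") return(pr$Cs[1])
  r1 <- pr$rho[1]; r2 <- pr$rho[2]
  cc <- (pr$Cs[1] * r2^2 - pr$Cs[2] * r1^2) / (r2^2 - r1^2)
  min(max(cc, 0), 1)   # extrapolation can stray a hair outside [0, 1]
}

#' Effectiveness factor of a steady bead field
#'
#' Ratio of the volume-averaged reaction rate in the bead to the rate at
#' surface conditions:
#' \deqn{\eta = 3(1+\beta)\int_0^1 \frac{C_s(\rho)}{1+\beta C_s(\rho)}
#'   \rho^2\, d\rho.}
#' \code{eta -> 1} as \code{phi -> 0} (reaction-rate control) and falls
#' toward 0 under internal-diffusion control.
#'
#' @param field a converged steady \code{"bead_field"}.
#' @return An object of class \code{"effectiveness_result"}: list with
#'   \code{eta}, \code{phi}, \code{beta}, \code{center_concentration}.
#' @examples
#' effectiveness_factor(steady_sphere_1d(1, 0, 64))$eta  # about coth(3) - 1/3
#' @export
effectiveness_factor <- function(field) {
  stopifnot(inherits(field, "bead_field"))
  if (!isTRUE(field$converged))
    stop("effectiveness factor requires a converged steady field")
  if (!is.na(field$tau))
    stop("effectiveness factor is defined for steady fields only")
  beta <- field$groups$beta
  f <- function(C) C / (1 + beta * C)
  if (field$type == "radial") {
    pr <- field_profile(field, "Cs")
    sf <- stats::splinefun(pr$rho, f(pr$Cs) * pr$rho^2, method = "natural")
    eta <- 3 * (1 + beta) * stats::integrate(sf, 0, 1,
                                             rel.tol = 1e-10)$value
  } else {
    # volume-weighted cell average; cell volumes ~ rho^2 sin(theta)
    w <- field$mesh$w
    eta <- (1 + beta) * sum(w * f(field$Cs)) / sum(w)
  }
  structure(list(eta = eta, phi = field$groups$phi, beta = beta,
                 center_concentration = center_concentration(field)),
            class = "effectiveness_result")
}

#' @export
print.effectiveness_result <- function(x, ...) {
  cat(sprintf("Effectiveness factor: eta = %.4f (phi = %g, beta = %g, centre Cs = %.4g)\n",
              x$eta, x$phi, x$beta, x$center_concentration))
  invisible(x)
}

#' First-order (beta = 0) closed-form reference profile
#'
#' In the first-order limit the steady radial problem has the classical
#' solution \code{C(rho) = sinh(3 phi rho) / (rho sinh(3 phi))}, evaluated
#' here in overflow-safe exponential form.
#'
#' @param phi Thiele modulus (> 0).
#' @param rho radii in \code{[0, 1]}.
#' @return Profile values; the removable singularity at \code{rho = 0} is
#'   filled with its limit \code{3 phi / sinh(3 phi)}.
#' @export
first_order_profile <- function(phi, rho) {
  if (phi <= 0) stop("'phi' must be positive")
  a <- 3 * phi
  # sinh(a rho)/sinh(a) = exp(a(rho-1)) * (1 - exp(-2 a rho)) / (1 - exp(-2a))
  ratio <- exp(a * (rho - 1)) * (1 - exp(-2 * a * rho)) / (1 - exp(-2 * a))
  out <- ratio / pmax(rho, .Machine$double.xmin)
  out[rho == 0] <- 2 * a * exp(-a) / (1 - exp(-2 * a))
  out
}

#' First-order closed-form effectiveness factor
#'
#' \code{eta(phi) = (1/phi) * (coth(3 phi) - 1/(3 phi))} for a sphere in
#' the first-order limit.
#'
#' @param phi Thiele modulus (> 0).
#' @return Effectiveness factor in \code{(0, 1]}.
#' @export
first_order_effectiveness <- function(phi) {
  if (any(phi <= 0)) stop("'phi' must be positive")
  a <- 3 * phi
  (1 / phi) * (1 / tanh(a) - 1 / a)
}
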