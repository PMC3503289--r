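#' Structured mesh of the bead's quarter cross-section
#'
#' Discretizes the axisymmetric quarter cross-section
#' \{(r_dot, z_dot): r_dot, z_dot >= 0, r_dot^2 + z_dot^2 <= 1\} of a unit
#' sphere on a spherical-polar mapped grid: radius rho in (0, 1] and polar
#' angle theta in (0, pi/2), with cell centres at
#' \code{rho_i = (i - 1/2)/n} and \code{theta_j = (j - 1/2) * (pi/2)/m}.
#' Under this mapping the curved Dirichlet surface becomes the straight
#' edge rho = 1 and the two symmetry boundaries (z-axis at theta = 0,
#' midplane at theta = pi/2) carry natural zero-flux conditions, so the
#' scheme never needs to cut cells against the circle.
#'
#' @param n radial resolution (cells across the radius). Must be >= 16:
#'   coarser grids cannot resolve the reaction-diffusion balance reliably.
#' @param m angular resolution; defaults to \code{n}.
#' @return An object of class \code{"axi_mesh"}: cell-centre coordinate
#'   vectors \code{rho}, \code{theta}, spacing \code{h}, \code{dtheta},
#'   matrices \code{r_dot}, \code{z_dot} (n x m) of Cartesian cell centres,
#'   a data frame \code{surface} of surface-face midpoints, and the cell
#'   volume weights \code{w} used for volume averaging.
#' @export
axi_mesh <- function(n, m = n) {
  if (n < 16) stop("mesh too coarse: radial resolution 'n' must be at least 16")
  if (m < 4) stop("angular resolution 'm' must be at least 4")
  h <- 1 / n
  dtheta <- (pi / 2) / m
  rho <- (seq_len(n) - 0.5) * h
  theta <- (seq_len(m) - 0.5) * dtheta
  r_dot <- outer(rho, sin(theta))
  z_dot <- outer(rho, cos(theta))
  # cell volume (axisymmetric, unit sphere octant scaling drops out on
  # averaging): w_ij = rho_i^2 sin(theta_j) h dtheta
  w <- outer(rho^2, sin(theta)) * h * dtheta
  structure(list(n = n, m = m, h = h, dtheta = dtheta,
                 rho = rho, theta = theta,
                 r_dot = r_dot, z_dot = z_dot, w = w,
                 surface = data.frame(r_dot = sin(theta), z_dot = cos(theta),
                                      tag = "surface")),
            class = "axi_mesh")
}

#' @export
print.axi_mesh <- function(x, ...) {
  cat(sprintf("Axisymmetric quarter-section mesh: %d x %d cells (radial x angular)\n",
              x$n, x$m))
  invisible(x)
}

# Sparse discrete operator for the axisymmetric Laplacian on an axi_mesh.
# In the (rho, theta) mapping the cylindrical-axisymmetric operator
# (1/r) d/dr (r d/dr) + d2/dz2 becomes the spherical Laplacian
# (1/rho^2) d/drho (rho^2 d/drho) + (1/(rho^2 sin)) d/dth (sin d/dth).
# Conservative finite volumes: inner radial face (rho = 0) and the axis
# face (theta = 0) carry identically zero flux; the midplane face
# (theta = pi/2) is zero-flux by symmetry; the surface face (rho = 1) is
# Dirichlet, entering through b_unit so that the action on a field C with
# boundary value g is  L %*% C + g * b_unit.
# Returns list(L = dgCMatrix (nm x nm), b_unit = numeric(nm)); unknowns are
# ordered cell (i, j) -> (j - 1) * n + i.
axi_operator <- function(mesh) {
  n <- mesh$n; m <- mesh$m; h <- mesh$h; dth <- mesh$dtheta
  rho <- mesh$rho; theta <- mesh$theta
  rf <- (0:n) * h                        # radial faces
  thf <- (0:m) * dth                     # angular faces
  N <- n * m
  I <- rep(seq_len(n), m)                # radial index of each unknown
  J <- rep(seq_len(m), each = n)         # angular index
  ri2 <- rho[I]^2
  # radial neighbour coefficients (outer face of cell n handled below)
  cp <- ifelse(I < n, rf[I + 1]^2 / (ri2 * h^2), 0)
  cm <- ifelse(I > 1, rf[I]^2 / (ri2 * h^2), 0)
  # angular neighbour coefficients; zero flux at theta = 0 and pi/2
  ap <- ifelse(J < m, sin(thf[J + 1]) / (sin(theta[J]) * dth^2), 0) / ri2
  am <- ifelse(J > 1, sin(thf[J]) / (sin(theta[J]) * dth^2), 0) / ri2
  diagv <- -(cp + cm + ap + am)
  b_unit <- numeric(N)
  # Dirichlet face at rho = 1: quadratic one-sided flux through the
  # boundary value g and the two innermost cell centres,
  # dC/drho|_1 = (8 g - 9 C_n + C_{n-1}) / (3 h); second order
  outer_cells <- which(I == n)
  diagv[outer_cells] <- diagv[outer_cells] - 3 / (ri2[outer_cells] * h^2)
  b_unit[outer_cells] <- 8 / (3 * ri2[outer_cells] * h^2)
  cm_extra <- numeric(N)
  cm_extra[outer_cells] <- 1 / (3 * ri2[outer_cells] * h^2)

  k <- seq_len(N)
  ii <- c(k, k[I < n], k[I > 1], k[J < m], k[J > 1])
  jj <- c(k, k[I < n] + 1L, k[I > 1] - 1L, k[J < m] + n, k[J > 1] - n)
  vv <- c(diagv, cp[I < n], (cm + cm_extra)[I > 1],
          ap[J < m], am[J > 1])
  L <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(N, N))
  list(L = L, b_unit = b_unit)
}

# Discrete operator for the radially symmetric Laplacian
# (1/rho^2) d/drho (rho^2 d/drho) on the node grid rho_i = i/n, i = 0..n-1
# (the surface node i = n is Dirichlet and eliminated). At the centre the
# regular limit 3 C'' is used: 6 (C_1 - C_0) / h^2.
radial_operator <- function(n) {
  h <- 1 / n
  rho <- (0:(n - 1)) * h
  N <- n
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  add <- function(a, b, v) {
    ii <<- c(ii, a); jj <<- c(jj, b); vv <<- c(vv, v)
  }
  b_unit <- numeric(N)
  # centre node (k = 1, rho = 0)
  add(1, 1, -6 / h^2); add(1, 2, 6 / h^2)
  for (i in 2:N) {                      # nodes rho = (i-1) h, i-1 = 1..n-1
    r <- rho[i]
    cp <- (r + h / 2)^2 / (r^2 * h^2)
    cm <- (r - h / 2)^2 / (r^2 * h^2)
    add(i, i, -(cp + cm))
    add(i, i - 1, cm)
    if (i < N) add(i, i + 1, cp) else b_unit[i] <- cp
  }
  L <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(N, N))
  list(L = L, b_unit = b_unit, rho = rho, h = h)
}
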