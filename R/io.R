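#' Write conversion series to a delimited text file
#'
#' One row per observation, header
#' \code{S0_g_per_L,t_min,St_g_per_L}; multiple series are concatenated.
#'
#' @param series a [conversion_series] or a list of them.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_conversion_series <- function(series, path) {
  if (inherits(series, "conversion_series")) series <- list(series)
  rows <- do.call(rbind, lapply(series, function(s) {
    data.frame(S0_g_per_L = s$S0, t_min = s$observations$t,
               St_g_per_L = s$observations$St)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read conversion series from a delimited text file
#'
#' Inverse of [write_conversion_series]: rows are grouped by their inlet
#' concentration, each group becoming one series (times sorted).
#'
#' @param path input file with columns
#'   \code{S0_g_per_L,t_min,St_g_per_L}.
#' @return A list of [conversion_series].
#' @export
read_conversion_series <- function(path) {
  d <- utils::read.csv(path)
  need <- c("S0_g_per_L", "t_min", "St_g_per_L")
  if (!all(need %in% names(d)))
    stop("expected columns ", paste(need, collapse = ", "))
  lapply(split(d, d$S0_g_per_L), function(g) {
    g <- g[order(g$t_min), ]
    conversion_series(g$S0_g_per_L[1], g$t_min, g$St_g_per_L)
  })
}

#' Write fitted kinetic parameters to a delimited text file
#'
#' Header \code{S0_g_per_L,Km_g_per_L,Vmax_g_per_L_min,k2_per_min,}
#' \code{r_squared,n_points}; the turnover column is filled when an enzyme
#' load is supplied and left \code{NA} otherwise.
#'
#' @param fits an \code{"mm_fit"} or list of them.
#' @param path output file path.
#' @param E0 optional enzyme load, g/L, used to derive the turnover number.
#' @return The fit table (data frame), invisibly; written to \code{path}.
#' @export
write_fit_table <- function(fits, path, E0 = NULL) {
  if (inherits(fits, "mm_fit")) fits <- list(fits)
  tab <- do.call(rbind, lapply(fits, function(f) {
    data.frame(S0_g_per_L = f$S0, Km_g_per_L = f$Km_hat,
               Vmax_g_per_L_min = f$Vmax_hat,
               k2_per_min = if (is.null(E0)) NA_real_
                            else turnover_number(f$Vmax_hat, E0),
               r_squared = f$r_squared, n_points = f$n_points)
  }))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(tab)
}

#' Write a bead field to a delimited text file
#'
#' Axisymmetric fields are written with header \code{r_dot,z_dot,Cs,Cp}
#' (optionally reflected through the midplane for rendering full
#' cross-sections); radial profiles with header \code{rho,Cs,Cp}.
#'
#' @param field a \code{"bead_field"}.
#' @param path output file path.
#' @param reflect reflect axisymmetric fields through z = 0.
#' @return The path, invisibly.
#' @export
write_field <- function(field, path, reflect = FALSE) {
  stopifnot(inherits(field, "bead_field"))
  if (field$type == "radial") {
    d <- data.frame(rho = field$mesh$rho, Cs = field$Cs, Cp = field$Cp)
  } else {
    d <- data.frame(r_dot = as.vector(field$mesh$r_dot),
                    z_dot = as.vector(field$mesh$z_dot),
                    Cs = as.vector(field$Cs), Cp = as.vector(field$Cp))
    if (reflect) {
      lower <- d[d$z_dot > 0, ]
      lower$z_dot <- -lower$z_dot
      d <- rbind(d, lower)
    }
  }
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
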