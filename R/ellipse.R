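#' Fit an ellipse to boundary points by direct least squares
#'
#' Fits the conic `A x^2 + B xy + C y^2 + D x + E y + F = 0` to a set of
#' 2-D points under the ellipse constraint `4AC - B^2 = 1` (Fitzgibbon's
#' direct method, in the numerically stable partitioned form of Halir and
#' Flusser), then converts the conic to geometric parameters. Coordinates
#' follow the image convention used throughout the package: the first
#' column is the row coordinate, the second the column coordinate, and the
#' orientation is the angle of the semi-major axis measured from the row
#' axis, canonicalized to `[0, pi)`.
#'
#' @param points two-column numeric matrix or data frame of boundary
#'   points, `(row, col)` per row. At least 6 non-collinear points.
#' @return an object of class `ellipse_fit`: a list with `center`
#'   (row, col), `a` (semi-major, px), `b` (semi-minor, px),
#'   `orientation` (radians in `[0, pi)`) and `rms` (root-mean-square
#'   approximate geometric residual, px).
#' @examples
#' phi <- seq(0, 2 * pi, length.out = 37)[-37]
#' pts <- cbind(50 + 20 * cos(phi), 80 + 12 * sin(phi))
#' fit_ellipse(pts)
#' @export
fit_ellipse <- function(points) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 2L) {
    rlang::abort("`points` must be a two-column numeric matrix (row, col).")
  }
  points <- points[stats::complete.cases(points), , drop = FALSE]
  n <- nrow(points)
  if (n < 6L) {
    rlang::abort("ellipse underdetermined: need at least 6 points.")
  }
  # centre for conditioning; undone below
  mx <- mean(points[, 1L]); my <- mean(points[, 2L])
  x <- points[, 1L] - mx
  y <- points[, 2L] - my
  if (max(abs(x)) < 1e-12 && max(abs(y)) < 1e-12) {
    rlang::abort("ellipse underdetermined: degenerate point set.")
  }

  d1 <- cbind(x^2, x * y, y^2)
  d2 <- cbind(x, y, 1)
  s1 <- crossprod(d1)
  s2 <- crossprod(d1, d2)
  s3 <- crossprod(d2)
  t_mat <- tryCatch(-solve(s3, t(s2)), error = function(e) NULL)
  if (is.null(t_mat)) {
    rlang::abort("ellipse underdetermined: degenerate (collinear?) point set.")
  }
  m <- s1 + s2 %*% t_mat
  # premultiply by inv(C1) for constraint 4AC - B^2 = 1
  m <- rbind(m[3L, ] / 2, -m[2L, ], m[1L, ] / 2)
  eg <- eigen(m)
  ev <- Re(eg$vectors)
  cond <- 4 * ev[1L, ] * ev[3L, ] - ev[2L, ]^2
  ok <- which(cond > 1e-12)
  if (length(ok) == 0L) {
    rlang::abort("ellipse underdetermined: no elliptical solution for this point set.")
  }
  a1 <- ev[, ok[1L]]
  coef <- c(a1, as.numeric(t_mat %*% a1))  # A B C D E F in centred coords

  geom <- conic_to_geometric(coef)
  if (is.null(geom)) {
    rlang::abort("ellipse underdetermined: conic is not a real ellipse.")
  }
  geom$center <- geom$center + c(mx, my)
  geom$rms <- ellipse_residual_rms(coef, x, y)
  structure(geom, class = "ellipse_fit")
}

# conic (A,B,C,D,E,F) -> center/semi-axes/orientation, or NULL if not an ellipse
conic_to_geometric <- function(k) {
  a <- k[1L]; b <- k[2L]; cc <- k[3L]; d <- k[4L]; e <- k[5L]; f <- k[6L]
  m2 <- matrix(c(2 * a, b, b, 2 * cc), 2L, 2L)
  if (abs(det(m2)) < 1e-14) return(NULL)
  center <- solve(m2, c(-d, -e))
  # constant term after translation to the center
  fc <- f + (d * center[1L] + e * center[2L]) / 2
  q <- matrix(c(a, b / 2, b / 2, cc), 2L, 2L)
  eq <- eigen(q, symmetric = TRUE)
  lam <- eq$values
  if (any(-fc / lam <= 0)) return(NULL)
  len <- sqrt(-fc / lam)              # semi-axis along each eigenvector
  i_maj <- which.max(len)
  v <- eq$vectors[, i_maj]
  ang <- atan2(v[2L], v[1L]) %% pi
  list(center = center, a = max(len), b = min(len), orientation = ang)
}

# approximate geometric residual: |Q(p)| / |grad Q(p)| per point
ellipse_residual_rms <- function(k, x, y) {
  q <- k[1L] * x^2 + k[2L] * x * y + k[3L] * y^2 + k[4L] * x + k[5L] * y + k[6L]
  gx <- 2 * k[1L] * x + k[2L] * y + k[4L]
  gy <- k[2L] * x + 2 * k[3L] * y + k[5L]
  g <- sqrt(gx^2 + gy^2)
  g[g < 1e-12] <- 1e-12
  sqrt(mean((q / g)^2))
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf(
    "<ellipse_fit> center = (%.2f, %.2f)  a = %.2f px  b = %.2f px  theta = %.1f deg  rms = %.3g px\n",
    x$center[1L], x$center[2L], x$a, x$b, x$orientation * 180 / pi, x$rms))
  invisible(x)
}

#' Points on an ellipse boundary
#'
#' Parametric points on an ellipse, in `(row, col)` image coordinates.
#' Mostly useful for building fixtures and overlays.
#'
#' @param center numeric length 2, `(row, col)`.
#' @param a,b semi-major and semi-minor axes (px).
#' @param orientation angle of the major axis from the row axis (radians).
#' @param n number of points, equally spaced in the parametric angle.
#' @return an `n x 2` matrix of `(row, col)` points.
#' @export
ellipse_points <- function(center, a, b, orientation = 0, n = 90L) {
  phi <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  xr <- a * cos(phi); yr <- b * sin(phi)
  ct <- cos(orientation); st <- sin(orientation)
  cbind(center[1L] + xr * ct - yr * st,
        center[2L] + xr * st + yr * ct)
}

# distance from ellipse center to its boundary along absolute angle theta
ellipse_ray_distance <- function(a, b, orientation, theta) {
  psi <- theta - orientation
  a * b / sqrt((b * cos(psi))^2 + (a * sin(psi))^2)
}
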