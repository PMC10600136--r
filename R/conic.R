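# Algebraic conic fitting by a generalized eigenvector method (Taubin's
# gradient-weighted normalization).  The conic A x^2 + B xy + C y^2 + D x +
# E y + F = 0 is found by minimizing the algebraic residual a' M a subject
# to the gradient normalization a' N a = 1, i.e. the generalized
# eigenproblem M a = lambda N a; the eigenvector of the smallest
# non-negative eigenvalue is the fit.  Data are centred and scaled
# internally for conditioning; coefficients are reported in original units
# with unit Euclidean norm.

#' Fit a conic section to scattered points
#'
#' @param x,y coordinates of at least 6 points.
#' @param prescale_x optional positive factor by which the abscissa is
#'   multiplied before fitting (a conditioning aid when `x` and `y` differ
#'   by many orders of magnitude); reported coefficients are always in the
#'   original units.
#' @return object of class `conic_fit`: list with `coeffs` (named A-F, unit
#'   norm, original units), `coeffs_fit` (coefficients in the fit frame,
#'   i.e. with the abscissa multiplied by `prescale_x`), `discriminant`
#'   (`B^2 - 4*A*C`, fit frame), `kind` (`"ellipse"`, `"parabola"`,
#'   `"hyperbola"` or `"degenerate"`; conic type is affine-invariant, so
#'   the fit-frame classification also holds in original units), `center`,
#'   `axis_angle` (radians, transverse/major axis), `vertices`, `foci`
#'   (2 x 2 matrices, hyperbola/ellipse only), `semi_axes` - all geometry
#'   in the fit frame - plus `rms_algebraic_residual` (dimensionless,
#'   evaluated in the internal normalized frame) and `n`.
#' @export
conic_fit <- function(x, y, prescale_x = 1) {
  ok <- is.finite(x) & is.finite(y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 6L) stop("conic fitting requires at least 6 finite points", call. = FALSE)
  if (!is.numeric(prescale_x) || prescale_x <= 0)
    stop("`prescale_x` must be positive", call. = FALSE)
  x <- x * prescale_x

  # scale-invariant collinearity check on the point cloud
  degen <- sd(x) == 0 || sd(y) == 0
  if (!degen) {
    cv <- stats::cov(cbind(x / sd(x), y / sd(y)))
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
    degen <- ev[1L] <= 0 || ev[2L] / ev[1L] < 1e-12
  }
  if (degen) {
    fit <- degenerate_conic(x, y)
    fit$coeffs_fit <- fit$coeffs
    fit$prescale_x <- prescale_x
    co <- conic_unscale(fit$coeffs, 0, 0, 1 / prescale_x, 1)
    fit$coeffs <- co / sqrt(sum(co^2))
    names(fit$coeffs) <- LETTERS[1:6]
    fit$n <- n
    return(fit)
  }

  mx <- mean(x); my <- mean(y)
  sx <- stats::sd(x); sy <- stats::sd(y)
  p <- (x - mx) / sx; q <- (y - my) / sy

  Z <- cbind(p^2, p * q, q^2, p, q, 1)
  M <- crossprod(Z) / n
  Gx <- cbind(2 * p, q, rep(0, n), rep(1, n), rep(0, n), rep(0, n))
  Gy <- cbind(rep(0, n), p, 2 * q, rep(0, n), rep(1, n), rep(0, n))
  N <- (crossprod(Gx) + crossprod(Gy)) / n

  # F has zero gradient: eliminate it first (Schur complement), then solve
  # the 5x5 generalized eigenproblem by Cholesky whitening of N11
  M11 <- M[1:5, 1:5]; m12 <- M[1:5, 6]; m22 <- M[6, 6]
  Mt <- M11 - tcrossprod(m12) / m22
  R <- tryCatch(chol(N[1:5, 1:5]),
                error = function(e) stop("degenerate conic: singular normalization matrix",
                                         call. = FALSE))
  K <- backsolve(R, t(backsolve(R, t(Mt), transpose = TRUE)), transpose = TRUE)
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  b <- eg$vectors[, 5L]                  # smallest eigenvalue
  a1 <- backsolve(R, b)
  aa <- c(a1, -sum(m12 * a1) / m22)
  rms <- sqrt(mean((Z %*% (aa / sqrt(sum(aa^2))))^2))

  # fit-frame coefficients: the (possibly prescaled) plot coordinates.
  # Classification and geometry are computed here, where the two axes are
  # commensurate; conic type is affine-invariant, so this is also the type
  # in original units.
  cf <- conic_unscale(aa, mx, my, sx, sy)
  cf <- cf / sqrt(sum(cf^2))
  if (cf[which.max(abs(cf))] < 0) cf <- -cf
  names(cf) <- LETTERS[1:6]
  # conic type is affine-invariant: classify in the standardized frame,
  # where the discriminant threshold is scale-free
  a_std <- aa / sqrt(sum(aa^2))
  disc_std <- a_std[2L]^2 - 4 * a_std[1L] * a_std[3L]
  kind <- if (abs(disc_std) < 1e-12) "parabola" else
    if (disc_std > 0) "hyperbola" else "ellipse"
  out <- conic_geometry(cf, kind)
  out$coeffs_fit <- cf
  out$prescale_x <- prescale_x
  # original-unit coefficients (undo the abscissa prescale)
  coeffs <- conic_unscale(cf, 0, 0, 1 / prescale_x, 1)
  coeffs <- coeffs / sqrt(sum(coeffs^2))
  names(coeffs) <- LETTERS[1:6]
  out$coeffs <- coeffs
  out$rms_algebraic_residual <- rms
  out$n <- n
  structure(out, class = "conic_fit")
}

# map conic coefficients in standardized coordinates p = (x - mx)/sx,
# q = (y - my)/sy back to raw (x, y) coordinates
conic_unscale <- function(a, mx, my, sx, sy) {
  A <- a[1]; B <- a[2]; C <- a[3]; D <- a[4]; E <- a[5]; F <- a[6]
  c(
    A / sx^2,
    B / (sx * sy),
    C / sy^2,
    -2 * A * mx / sx^2 - B * my / (sx * sy) + D / sx,
    -2 * C * my / sy^2 - B * mx / (sx * sy) + E / sy,
    A * mx^2 / sx^2 + B * mx * my / (sx * sy) + C * my^2 / sy^2 -
      D * mx / sx - E * my / sy + F
  )
}

degenerate_conic <- function(x, y) {
  # points are (numerically) collinear: return the squared best-fit line
  # l(x, y)^2 = 0 as a degenerate conic, flagged rather than an error
  d <- prcomp(cbind(x, y))$rotation[, 2L]      # line normal
  f <- -(d[1L] * mean(x) + d[2L] * mean(y))
  a <- c(d[1L]^2, 2 * d[1L] * d[2L], d[2L]^2, 2 * d[1L] * f, 2 * d[2L] * f, f^2)
  a <- a / sqrt(sum(a^2))
  names(a) <- LETTERS[1:6]
  structure(list(coeffs = a, discriminant = 0, kind = "degenerate",
                 center = NULL, axis_angle = NA_real_, vertices = NULL,
                 foci = NULL, semi_axes = NULL,
                 rms_algebraic_residual = NA_real_),
            class = "conic_fit")
}

# for central conics, compute center / axes / vertices / foci by
# principal-axis transformation; `kind` comes from the standardized-frame
# classification (affine-invariant)
conic_geometry <- function(coeffs, kind = NULL) {
  A <- coeffs[["A"]]; B <- coeffs[["B"]]; C <- coeffs[["C"]]
  D <- coeffs[["D"]]; E <- coeffs[["E"]]; F <- coeffs[["F"]]
  disc <- B^2 - 4 * A * C
  if (is.null(kind))
    kind <- if (abs(disc) < 1e-12) "parabola" else
      if (disc > 0) "hyperbola" else "ellipse"
  out <- list(coeffs = coeffs, discriminant = disc, kind = kind,
              center = NULL, axis_angle = NA_real_, vertices = NULL,
              foci = NULL, semi_axes = NULL)
  if (kind == "parabola") return(out)

  Q2 <- matrix(c(A, B / 2, B / 2, C), 2L)
  ctr <- tryCatch(drop(solve(Q2, -c(D, E) / 2)),
                  error = function(e) NULL)
  if (is.null(ctr)) return(out)
  F0 <- F + (D * ctr[1L] + E * ctr[2L]) / 2
  eg <- eigen(Q2, symmetric = TRUE)
  lam <- eg$values; vec <- eg$vectors
  out$center <- ctr
  if (abs(F0) < 1e-14) return(out)       # degenerate central conic (point/lines)
  # axis equation: lam1 u^2 + lam2 v^2 = -F0; denominators -F0/lam
  den <- -F0 / lam
  if (kind == "hyperbola") {
    tr <- which(den > 0)                 # transverse axis direction
    if (length(tr) != 1L) return(out)
    co <- 3L - tr
    a2 <- den[tr]; b2 <- -den[co]
    dir <- vec[, tr]
    out$axis_angle <- atan2(dir[2L], dir[1L]) %% pi
    out$semi_axes <- c(transverse = sqrt(a2), conjugate = sqrt(b2))
    out$vertices <- rbind(ctr + sqrt(a2) * dir, ctr - sqrt(a2) * dir)
    cf <- sqrt(a2 + b2)
    out$foci <- rbind(ctr + cf * dir, ctr - cf * dir)
  } else {
    if (any(den <= 0)) return(out)       # imaginary ellipse
    mj <- which.max(den); mn <- 3L - mj
    dir <- vec[, mj]
    out$axis_angle <- atan2(dir[2L], dir[1L]) %% pi
    out$semi_axes <- c(major = sqrt(den[mj]), minor = sqrt(den[mn]))
    out$vertices <- rbind(ctr + sqrt(den[mj]) * dir, ctr - sqrt(den[mj]) * dir)
    cf <- sqrt(den[mj] - den[mn])
    out$foci <- rbind(ctr + cf * dir, ctr - cf * dir)
  }
  out
}

#' Evaluate a conic's algebraic form at points
#'
#' @param fit a [conic_fit()] (or named length-6 coefficient vector).
#' @param x,y coordinates.
#' @return numeric vector `A x^2 + B xy + C y^2 + D x + E y + F`.
#' @export
conic_residual <- function(fit, x, y) {
  a <- if (inherits(fit, "conic_fit")) fit$coeffs else fit
  a[1] * x^2 + a[2] * x * y + a[3] * y^2 + a[4] * x + a[5] * y + a[6]
}

#' @export
print.conic_fit <- function(x, ...) {
  cat(sprintf("<conic_fit> kind = %s, discriminant = %.3g, n = %d\n",
              x$kind, x$discriminant, if (is.null(x$n)) NA_integer_ else x$n))
  cat("coefficients (A..F):", signif(x$coeffs, 4), "\n")
  if (!is.null(x$vertices)) {
    cat("vertices:\n"); print(signif(x$vertices, 6))
  }
  invisible(x)
}

#' Conic fits grouped by pre- or post-transition state
#'
#' Splits the 100 transition types into 10 groups of 10 sharing the same
#' pre-transition (or post-transition) state and fits one conic per group.
#' Degenerate or failing groups are flagged, not fatal.
#'
#' @param x,y numeric 100-vectors of coefficient values (index = type `k`).
#' @param group_by `"pre_state"` or `"post_state"`.
#' @param prescale_x passed to [conic_fit()].
#' @return named list of 10 elements, each a `conic_fit` or a
#'   `try-error`-like list with `kind = "failed"`.
#' @export
per_state_conic_fits <- function(x, y, group_by = c("pre_state", "post_state"),
                                 prescale_x = 1) {
  group_by <- match.arg(group_by)
  stopifnot(length(x) == 100L, length(y) == 100L)
  dec <- decode_transition(1:100)
  g <- if (group_by == "pre_state") dec$s1 else dec$s2
  out <- lapply(1:10, function(s) {
    idx <- which(g == s)
    tryCatch(conic_fit(x[idx], y[idx], prescale_x = prescale_x),
             error = function(e) list(kind = "failed", message = conditionMessage(e)))
  })
  names(out) <- paste0("state_", 1:10)
  out
}
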