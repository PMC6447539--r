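# Model-independent analysis: regularized indirect Fourier transformation to
# the pair-distance distribution p(r), radius of gyration from its moments,
# and power-law / Porod slope classification.

# forward operator: I(q) = 4 pi int_0^Dmax p(r) sin(qr)/(qr) dr, trapezoid in r
.ift_kernel <- function(q, r) {
  dr <- r[2] - r[1]
  K <- outer(q, r, function(qq, rr) {
    x <- qq * rr
    ifelse(x < 1e-10, 1, sin(x) / x)
  })
  4 * pi * dr * K
}

#' Indirect Fourier transform of a scattering curve
#'
#' Solves `I(q) = 4 pi int p(r) sin(qr)/(qr) dr` on a uniform r grid in
#' `[0, D_max]` as a linear inverse problem with a second-derivative
#' (smoothness) penalty of weight `alpha` and endpoint constraints
#' `p(0) = p(D_max) = 0`. Negative lobes of p(r) are permitted (bilayer X-ray
#' contrast can produce them). When `alpha` is `NULL` it is selected by an
#' L-curve scan: the solution of maximum distance from the straight line
#' joining the extremes of the (log residual, log roughness) curve.
#'
#' @param curve a [scattering_curve()].
#' @param D_max assumed maximum particle dimension, A.
#' @param n_r number of r grid points (default 101).
#' @param alpha regularization weight (>= 0), or `NULL` for automatic
#'   selection.
#' @param q_window optional `c(q_min, q_max)` restriction (partial-range
#'   analysis, e.g. low-q only in the presence of structure-factor peaks).
#' @return object of class `pddf`: `r`, `p`, `D_max`, `alpha`, `q`, `I_fit`,
#'   `residual_rms` (sigma-weighted when uncertainties exist), and `flag`
#'   (non-NULL when residuals look systematic, typically a too-small D_max).
#' @export
ift <- function(curve, D_max, n_r = 101, alpha = NULL, q_window = NULL) {
  stopifnot(inherits(curve, "scattering_curve"), D_max > 0, n_r >= 20)
  q <- curve$q; I <- curve$I
  sig <- if (is.null(curve$sigma)) rep(1, length(q)) else curve$sigma
  if (!is.null(q_window)) {
    keep <- q >= q_window[1] & q <= q_window[2]
    q <- q[keep]; I <- I[keep]; sig <- sig[keep]
  }
  r <- seq(0, D_max, length.out = n_r)
  Kfull <- .ift_kernel(q, r)
  K <- Kfull[, -c(1, n_r), drop = FALSE]   # p = 0 at both endpoints
  W <- 1 / sig
  Kw <- K * W
  Iw <- I * W
  m <- n_r - 2
  # second differences on the interior, with the zero endpoints implied
  L <- matrix(0, m, m)
  for (i in seq_len(m)) {
    L[i, i] <- -2
    if (i > 1) L[i, i - 1] <- 1
    if (i < m) L[i, i + 1] <- 1
  }
  M <- crossprod(Kw)
  Rg <- crossprod(L)
  rhs <- crossprod(Kw, Iw)
  solve_alpha <- function(a) {
    p <- tryCatch(solve(M + a * Rg, rhs), error = function(e) NULL)
    if (is.null(p)) p <- qr.solve(M + a * Rg, rhs, tol = 1e-300)
    as.numeric(p)
  }
  aref <- sum(diag(M)) / max(sum(diag(Rg)), .Machine$double.eps)
  if (is.null(alpha)) {
    grid <- aref * 10^seq(-8, 3, length.out = 23)
    sols <- lapply(grid, solve_alpha)
    rho <- vapply(sols, function(p) sqrt(sum((Kw %*% p - Iw)^2)), 0)
    eta <- vapply(sols, function(p) sqrt(sum((L %*% p)^2)), 0)
    lr <- log10(pmax(rho, 1e-300)); le <- log10(pmax(eta, 1e-300))
    # distance from the chord through the endpoints of the L-curve
    v <- c(lr[length(lr)] - lr[1], le[length(le)] - le[1])
    v <- v / sqrt(sum(v^2))
    dist <- abs((lr - lr[1]) * v[2] - (le - le[1]) * v[1])
    alpha <- grid[which.max(dist)]
  }
  stopifnot(alpha >= 0)
  p_int <- solve_alpha(alpha)
  p <- c(0, p_int, 0)
  I_fit <- as.numeric(Kfull %*% p)
  resid <- (I_fit - I) * W
  rms <- sqrt(mean(resid^2))
  flag <- NULL
  if (!is.null(curve$sigma) && rms > 3) {
    flag <- "systematic residuals: D_max may be too small"
  }
  sign_changes <- sum(abs(diff(sign(p[p != 0]))) > 0)
  if (sign_changes > n_r / 3) {
    flag <- paste(c(flag, "strongly oscillating p(r)"), collapse = "; ")
  }
  structure(list(r = r, p = p, D_max = D_max, alpha = alpha, q = q,
                 I_fit = I_fit, residual_rms = rms, flag = flag),
            class = "pddf")
}

#' @export
print.pddf <- function(x, ...) {
  cat(sprintf("<pddf> %d r points on [0, %.4g] A, alpha = %.3g, residual RMS %.3g%s\n",
              length(x$r), x$D_max, x$alpha, x$residual_rms,
              if (is.null(x$flag)) "" else paste0("  [", x$flag, "]")))
  invisible(x)
}

#' Forward-transform a p(r) back to intensity
#'
#' @param pddf a [ift()] result (or any list with `r`, `p` on a uniform grid).
#' @param q momentum-transfer grid, 1/A.
#' @return intensity vector.
#' @export
pddf_intensity <- function(pddf, q) {
  as.numeric(.ift_kernel(q, pddf$r) %*% pddf$p)
}

#' Radius of gyration from the pair-distance distribution
#'
#' `R_G^2 = int p(r) r^2 dr / (2 int p(r) dr)` by trapezoid quadrature.
#' For an ideal thin spherical shell of radius R this gives R_G = R; for a
#' solid sphere, `sqrt(3/5) R`.
#'
#' @param pddf a [ift()] result.
#' @return R_G in A.
#' @export
radius_of_gyration <- function(pddf) {
  r <- pddf$r; p <- pddf$p
  trapz <- function(y) sum((y[-1] + y[-length(y)]) / 2 * diff(r))
  denom <- trapz(p)
  if (abs(denom) < .Machine$double.eps) stop("p(r) integrates to zero")
  rg2 <- trapz(p * r^2) / (2 * denom)
  if (rg2 < 0) stop("negative second moment; p(r) not interpretable")
  sqrt(rg2)
}

.slope_labels <- c("cylinders", "lamellae (disks)", "3D fractal-like",
                   "sharp interfaces (Porod)")

#' Power-law exponents and Porod constant of a scattering curve
#'
#' Log-log linear fit `I ~ q^-m` in each window, with the conventional
#' structural reading m = 1 cylinders, 2 lamellae (disks), 3 fractal-like,
#' 4 sharp interfaces (Porod). The Porod constant is the median of `q^4 I`
#' over the highest-q window. Non-positive intensities are excluded with a
#' warning; exponents outside `[0, 4.5]` are flagged.
#'
#' @param curve a [scattering_curve()].
#' @param windows list of `c(q_lo, q_hi)` windows (>= 5 points each).
#' @return object of class `slope_report`: data frame `slopes` with columns
#'   `q_lo`, `q_hi`, `m`, `label`, `flagged`, plus `porod_constant`.
#' @export
power_law_slopes <- function(curve, windows) {
  stopifnot(inherits(curve, "scattering_curve"), length(windows) >= 1)
  qmax_of <- vapply(windows, function(w) w[2], 0)
  rows <- lapply(windows, function(w) {
    keep <- curve$q >= w[1] & curve$q <= w[2]
    q <- curve$q[keep]; I <- curve$I[keep]
    pos <- I > 0
    if (any(!pos)) {
      warning("excluding ", sum(!pos), " non-positive intensities in window [",
              w[1], ", ", w[2], "]")
    }
    q <- q[pos]; I <- I[pos]
    if (length(q) < 5) stop("fewer than 5 usable points in window")
    m <- -coef(lm(log(I) ~ log(q)))[[2]]
    lab <- .slope_labels[pmin(pmax(round(m), 1), 4)]
    data.frame(q_lo = w[1], q_hi = w[2], m = m, label = lab,
               flagged = m < 0 | m > 4.5)
  })
  hw <- windows[[which.max(qmax_of)]]
  keep <- curve$q >= hw[1] & curve$q <= hw[2] & curve$I > 0
  porod <- median(curve$q[keep]^4 * curve$I[keep])
  structure(list(slopes = do.call(rbind, rows), porod_constant = porod),
            class = "slope_report")
}

#' @export
print.slope_report <- function(x, ...) {
  print(x$slopes)
  cat(sprintf("Porod constant (median q^4 I, highest window): %.4g\n",
              x$porod_constant))
  invisible(x)
}
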