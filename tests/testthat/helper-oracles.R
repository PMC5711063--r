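# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: the gamma oracle is an exhaustive per-point
# search, the blur oracle integrates the arcsine position density by
# quadrature, and the affine oracle solves the normal equations directly.

# exhaustive brute-force global gamma on small grids
brute_gamma <- function(eval_grid, ref_grid, dose_tol = 3, dta = 3,
                        eval_region = NULL, search_radius = 3 * dta,
                        step = 0.15) {
  refmax <- max(ref_grid$dose)
  crit <- dose_tol / 100 * refmax
  xs <- ref_grid$x
  ys <- ref_grid$y
  if (is.null(eval_region)) eval_region <- c(range(xs), range(ys))
  ix <- which(xs >= eval_region[1] & xs <= eval_region[2])
  iy <- which(ys >= eval_region[3] & ys <= eval_region[4])
  interp <- function(px, py) {
    # bilinear lookup on the evaluated grid; NA outside
    fx <- (px - xs[1]) / ref_grid$spacing
    fy <- (py - ys[1]) / ref_grid$spacing
    jx <- floor(fx); jy <- floor(fy)
    if (jx < 0 || jy < 0 || jx >= length(xs) - 1 || jy >= length(ys) - 1) {
      return(NA_real_)
    }
    ax <- fx - jx; ay <- fy - jy
    E <- eval_grid$dose
    (1 - ay) * ((1 - ax) * E[jy + 1, jx + 1] + ax * E[jy + 1, jx + 2]) +
      ay * ((1 - ax) * E[jy + 2, jx + 1] + ax * E[jy + 2, jx + 2])
  }
  offs <- seq(-search_radius, search_radius, by = step)
  g <- matrix(NA_real_, length(iy), length(ix))
  for (a in seq_along(iy)) {
    for (b in seq_along(ix)) {
      x0 <- xs[ix[b]]; y0 <- ys[iy[a]]
      d0 <- ref_grid$dose[iy[a], ix[b]]
      best <- Inf
      for (dy in offs) {
        for (dx in offs) {
          d2 <- (dx^2 + dy^2) / dta^2
          if (d2 > (search_radius / dta)^2 || d2 >= best) next
          ev <- interp(x0 + dx, y0 + dy)
          if (is.na(ev)) next
          gg <- d2 + ((ev - d0) / crit)^2
          if (gg < best) best <- gg
        }
      }
      g[a, b] <- sqrt(best)
    }
  }
  list(gamma = g, pass_pct = 100 * mean(g <= 1 + 1e-9))
}

# blurred 1D profile for full-period sinusoidal motion: convolution of the
# static edge profile with the arcsine position density, by quadrature over
# phase (u = A sin(phi))
arcsine_blur_profile <- function(x, amplitude, width, sigma, n_phi = 4001) {
  phi <- seq(-pi / 2, pi / 2, length.out = n_phi)
  w <- rep(1, n_phi); w[c(1, n_phi)] <- 0.5           # trapezoid weights
  pxfun <- function(u) {
    s <- sigma * sqrt(2)
    e <- function(z) 0.5 * (pracma_erf((z + width / 2) / s) -
                              pracma_erf((z - width / 2) / s))
    e(u) / e(0)
  }
  vapply(x, function(x0) {
    sum(w * pxfun(x0 - amplitude * sin(phi))) / sum(w)
  }, numeric(1))
}

pracma_erf <- function(z) 2 * pnorm(z * sqrt(2)) - 1

# direct normal-equation solution of target ~ gain * surrogate + shift
normal_eq_affine <- function(s, x) {
  n <- length(s)
  A <- matrix(c(n, sum(s), sum(s), sum(s^2)), 2, 2)
  b <- c(sum(x), sum(s * x))
  sol <- solve(A, b)
  list(shift = sol[1], gain = sol[2])
}

# small smooth random dose grid for gamma cross-checks
random_dose_grid <- function(n = 21, spacing = 1, seed = 1) {
  set.seed(seed)
  spec <- dose_grid_spec(extent = (n - 1) * spacing, spacing = spacing)
  xs <- spec$x
  f <- outer(ys <- spec$y, xs, function(y, x) {
    100 * exp(-((x - 1)^2 + (y + 0.5)^2) / 60) +
      20 * sin(x / 4) * cos(y / 5) + 25
  })
  dose_grid(pmax(f, 0), spec)
}
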