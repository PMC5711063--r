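#' Isodose area
#'
#' Pixel-counted area receiving at least `level` percent of a reference
#' dose.  All arms of one experiment are referenced to the standstill
#' maximum, so a fully blurred film can reach a 95% area of 0 cm2.
#'
#' @param grid a [dose_grid].
#' @param level isodose level in percent, 0 < level < 100.
#' @param reference_max reference dose in cGy (the standstill grid maximum),
#'   > 0.
#' @return Area in cm2.
#' @export
isodose_area <- function(grid, level, reference_max) {
  if (!inherits(grid, "dose_grid")) {
    stop("`grid` must be a dose_grid", call. = FALSE)
  }
  if (!is.finite(level) || level <= 0 || level >= 100) {
    stop("`level` must be in (0, 100)", call. = FALSE)
  }
  if (!is.finite(reference_max) || reference_max <= 0) {
    stop("`reference_max` must be > 0", call. = FALSE)
  }
  sum(grid$dose >= level / 100 * reference_max) * grid$spacing^2 / 100
}

#' Isodose-area improvement from compensation
#'
#' The change in isodose area gained by compensation, expressed as a
#' percentage of the standstill area:
#' `100 * (area_comp - area_uncomp) / area_standstill`.
#'
#' @param area_comp,area_uncomp,area_standstill areas in cm2;
#'   `area_standstill > 0`.
#' @return Improvement in percent (unrounded).
#' @examples
#' improvement(4.6, 3.78, 5.36)   # 15.3 after rounding to one decimal
#' improvement(4.12, 0, 5.36)     # 76.9
#' @export
improvement <- function(area_comp, area_uncomp, area_standstill) {
  if (any(!is.finite(area_standstill)) || any(area_standstill <= 0)) {
    stop("`area_standstill` must be > 0", call. = FALSE)
  }
  100 * (area_comp - area_uncomp) / area_standstill
}

#' Mean dose inside the nominal field, relative to standstill
#'
#' Mean dose over the nominal field rectangle, as a percentage of the
#' standstill mean over the same rectangle.  Motion blurring always lowers
#' this below 100%.
#'
#' @param grid evaluated [dose_grid].
#' @param reference standstill [dose_grid] on the same raster.
#' @param field_rect `c(xmin, xmax, ymin, ymax)` in mm (default the
#'   3 x 3 cm field).
#' @return Mean field dose in percent of the standstill mean.
#' @export
mean_field_dose <- function(grid, reference,
                            field_rect = c(-15, 15, -15, 15)) {
  if (!inherits(grid, "dose_grid") || !inherits(reference, "dose_grid")) {
    stop("`grid` and `reference` must be dose_grids", call. = FALSE)
  }
  if (!identical(dim(grid$dose), dim(reference$dose))) {
    stop("grid geometries do not match", call. = FALSE)
  }
  ix <- which(grid$x >= field_rect[1] & grid$x <= field_rect[2])
  iy <- which(grid$y >= field_rect[3] & grid$y <= field_rect[4])
  100 * mean(grid$dose[iy, ix]) / mean(reference$dose[iy, ix])
}

#' Gamma analysis parameters
#'
#' @param dose_tol dose-difference criterion in percent of the reference
#'   (standstill) maximum (default 3).
#' @param dta distance-to-agreement criterion in mm (default 3).
#' @param eval_region `c(xmin, xmax, ymin, ymax)` in mm over which
#'   reference points are evaluated (default the nominal 3 x 3 cm field);
#'   `NULL` evaluates the whole grid.
#' @param search_radius spatial search radius in mm (default `3 * dta`).
#' @param interp_step step of the interpolated spatial search in mm
#'   (default `dta / 10`; must be <= `dta / 5`).
#' @return A `gamma_params` list.
#' @export
gamma_params <- function(dose_tol = 3, dta = 3,
                         eval_region = c(-15, 15, -15, 15),
                         search_radius = 3 * dta, interp_step = dta / 10) {
  if (dose_tol <= 0 || dta <= 0) {
    stop("`dose_tol` and `dta` must be > 0", call. = FALSE)
  }
  if (interp_step > dta / 5) {
    stop("`interp_step` must be <= dta / 5", call. = FALSE)
  }
  if (search_radius < dta) {
    stop("`search_radius` must be >= dta", call. = FALSE)
  }
  structure(list(dose_tol = dose_tol, dta = dta, eval_region = eval_region,
                 search_radius = search_radius, interp_step = interp_step),
            class = "gamma_params")
}

#' Global 2D gamma index (dose difference / distance to agreement)
#'
#' For each reference point `r` inside the evaluation region,
#' `gamma(r) = min over r'` within the search radius of
#' `sqrt(|r - r'|^2 / dta^2 + (D_eval(r') - D_ref(r))^2 / (tol * refmax)^2)`,
#' the evaluated dose bilinearly interpolated on a lattice of pitch
#' `interp_step`.  A point passes when `gamma <= 1`; the passing rate is the
#' percentage of evaluated reference points that pass.  Normalisation is
#' global: `tol` percent of the reference grid maximum.
#'
#' @param eval_grid evaluated [dose_grid] (the motion arm).
#' @param ref_grid reference [dose_grid] (the standstill arm), same raster.
#' @param p a [gamma_params].
#' @return A list with `gamma` (matrix over the evaluation region, with
#'   coordinate vectors `x` and `y`) and `pass_pct`.
#' @export
gamma_index <- function(eval_grid, ref_grid, p = gamma_params()) {
  if (!inherits(eval_grid, "dose_grid") || !inherits(ref_grid, "dose_grid")) {
    stop("grids must be dose_grids", call. = FALSE)
  }
  if (!identical(dim(eval_grid$dose), dim(ref_grid$dose)) ||
      max(abs(eval_grid$x - ref_grid$x)) > 1e-9 ||
      max(abs(eval_grid$y - ref_grid$y)) > 1e-9) {
    stop("grid geometries do not match", call. = FALSE)
  }
  refmax <- max(ref_grid$dose)
  if (refmax <= 0) stop("reference grid maximum must be > 0", call. = FALSE)
  dose_crit <- p$dose_tol / 100 * refmax

  if (is.null(p$eval_region)) {
    ix <- seq_along(ref_grid$x)
    iy <- seq_along(ref_grid$y)
  } else {
    ix <- which(ref_grid$x >= p$eval_region[1] &
                  ref_grid$x <= p$eval_region[2])
    iy <- which(ref_grid$y >= p$eval_region[3] &
                  ref_grid$y <= p$eval_region[4])
  }
  if (length(ix) == 0L || length(iy) == 0L) {
    stop("empty evaluation region", call. = FALSE)
  }
  dref <- ref_grid$dose[iy, ix, drop = FALSE]
  sp <- ref_grid$spacing
  nx <- length(ref_grid$x)
  ny <- length(ref_grid$y)

  # pad the evaluated dose so every shifted lookup stays in bounds; padded
  # cells are NA and contribute an infinite gamma (no dose information there)
  pad <- ceiling(p$search_radius / sp) + 2L
  E <- matrix(NA_real_, ny + 2L * pad, nx + 2L * pad)
  E[pad + seq_len(ny), pad + seq_len(nx)] <- eval_grid$dose

  offs <- seq(-p$search_radius, p$search_radius, by = p$interp_step)
  g2 <- matrix(Inf, nrow(dref), ncol(dref))
  for (dy in offs) {
    for (dx in offs) {
      d2 <- (dx * dx + dy * dy) / p$dta^2
      if (d2 > (p$search_radius / p$dta)^2 + 1e-12) next
      if (d2 >= max(g2)) next  # cannot improve any point
      # constant fractional shift: bilinear weights shared by all points
      fx <- dx / sp
      fy <- dy / sp
      jx <- floor(fx); ax <- fx - jx
      jy <- floor(fy); ay <- fy - jy
      rsel <- pad + iy + jy
      csel <- pad + ix + jx
      ev <- (1 - ay) * (1 - ax) * E[rsel, csel, drop = FALSE] +
        (1 - ay) * ax * E[rsel, csel + 1L, drop = FALSE] +
        ay * (1 - ax) * E[rsel + 1L, csel, drop = FALSE] +
        ay * ax * E[rsel + 1L, csel + 1L, drop = FALSE]
      gg <- d2 + ((ev - dref) / dose_crit)^2
      gg[is.na(gg)] <- Inf
      g2 <- pmin(g2, gg)
    }
  }
  gamma <- sqrt(g2)
  list(gamma = gamma, x = ref_grid$x[ix], y = ref_grid$y[iy],
       pass_pct = 100 * mean(gamma <= 1 + 1e-9))
}

#' Dosimetric summary of one experiment arm
#'
#' @param grid evaluated [dose_grid].
#' @param standstill standstill reference [dose_grid].
#' @param gp a [gamma_params].
#' @param field_rect nominal field rectangle in mm.
#' @return A `dose_report` list: `area95`, `area5` (cm2),
#'   `mean_field_dose_pct`, `gamma_pass` (percent).
#' @export
dose_report <- function(grid, standstill, gp = gamma_params(),
                        field_rect = c(-15, 15, -15, 15)) {
  refmax <- max(standstill$dose)
  structure(list(
    area95 = isodose_area(grid, 95, refmax),
    area5 = isodose_area(grid, 5, refmax),
    mean_field_dose_pct = mean_field_dose(grid, standstill, field_rect),
    gamma_pass = gamma_index(grid, standstill, gp)$pass_pct
  ), class = "dose_report")
}
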