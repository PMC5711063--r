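erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Static beam model
#'
#' A separable broad-beam dose model for the 3 x 3 cm field:
#' `D(x, y) = norm_dose * Px(x) * Py(y)` with
#' `P(u) = E(u) / E(0)`, `E(u) = 0.5 * (erf((u + w/2) / (sigma * sqrt(2))) -
#' erf((u - w/2) / (sigma * sqrt(2))))`, `w` the field dimension and `sigma`
#' the penumbra width.  The profile is normalised to 1 at the field centre,
#' so the centre pixel of the static grid receives exactly `norm_dose`.
#'
#' @param field_x,field_y field dimensions in mm (default 30 x 30 mm;
#'   `field_x` is the superior-inferior axis along which motion occurs).
#' @param penumbra_sigma penumbra width in mm, > 0.  Usually set by
#'   [calibrate_penumbra()] rather than by hand.
#' @param dose_rate dose rate in cGy/s.  The reference delivery is 300 cGy
#'   in 44.4 s, so the default is 300 / 44.4.
#' @param norm_dose nominal delivered dose at the field centre in cGy.
#' @return A `beam_model` list.
#' @export
beam_model <- function(field_x = 30, field_y = 30, penumbra_sigma = 3,
                       dose_rate = 300 / 44.4, norm_dose = 300) {
  if (field_x <= 0 || field_y <= 0) {
    stop("field dimensions must be > 0", call. = FALSE)
  }
  if (!is.finite(penumbra_sigma) || penumbra_sigma <= 0) {
    stop("`penumbra_sigma` must be > 0", call. = FALSE)
  }
  if (dose_rate <= 0 || norm_dose <= 0) {
    stop("`dose_rate` and `norm_dose` must be > 0", call. = FALSE)
  }
  structure(list(field_x = field_x, field_y = field_y,
                 penumbra_sigma = penumbra_sigma,
                 dose_rate = dose_rate, norm_dose = norm_dose),
            class = "beam_model")
}

# normalised 1D edge profile, P(0) = 1
beam_profile_1d <- function(u, width, sigma) {
  s <- sigma * sqrt(2)
  e <- function(z) 0.5 * (erf((z + width / 2) / s) - erf((z - width / 2) / s))
  e(u) / e(0)
}

#' Dose grid specification and container
#'
#' `dose_grid_spec()` describes a square pixel raster centred on the field
#' centre; `dose_grid()` wraps a dose matrix on such a raster.  Rows index
#' `y`, columns index `x` (the motion axis); both coordinate vectors are in
#' mm relative to the field centre.
#'
#' @param extent grid side length in mm (default 100 mm, covering the
#'   80 mm profile axis with margin).
#' @param spacing pixel spacing in mm (default 0.25 mm).
#' @return `dose_grid_spec`: a list with `x`, `y`, `spacing`.
#' @export
dose_grid_spec <- function(extent = 100, spacing = 0.25) {
  if (extent <= 0 || spacing <= 0) {
    stop("`extent` and `spacing` must be > 0", call. = FALSE)
  }
  half <- floor(extent / 2 / spacing)
  coords <- seq(-half, half) * spacing
  structure(list(x = coords, y = coords, spacing = spacing),
            class = "dose_grid_spec")
}

#' @rdname dose_grid_spec
#' @param dose numeric matrix of dose values (cGy), `length(y)` rows by
#'   `length(x)` columns, all >= 0.
#' @param spec a `dose_grid_spec`.
#' @param units dose units string.
#' @export
dose_grid <- function(dose, spec, units = "cGy") {
  if (!is.matrix(dose) || nrow(dose) != length(spec$y) ||
      ncol(dose) != length(spec$x)) {
    stop("`dose` must be a length(y) x length(x) matrix", call. = FALSE)
  }
  if (any(!is.finite(dose)) || any(dose < 0)) {
    stop("dose must be finite and >= 0", call. = FALSE)
  }
  structure(list(x = spec$x, y = spec$y, spacing = spec$spacing,
                 dose = dose, units = units),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %d x %d px @ %g mm, max %.4g %s\n",
              length(x$y), length(x$x), x$spacing, max(x$dose), x$units))
  invisible(x)
}

#' Static (standstill) dose distribution
#'
#' @param beam a [beam_model].
#' @param spec a [dose_grid_spec]; must cover the field.
#' @return A [dose_grid] with the separable static dose.
#' @export
static_dose <- function(beam, spec) {
  if (diff(range(spec$x)) < beam$field_x ||
      diff(range(spec$y)) < beam$field_y) {
    stop("grid smaller than the field", call. = FALSE)
  }
  px <- beam_profile_1d(spec$x, beam$field_x, beam$penumbra_sigma)
  py <- beam_profile_1d(spec$y, beam$field_y, beam$penumbra_sigma)
  dose_grid(beam$norm_dose * outer(py, px), spec)
}

#' Calibrate the penumbra width to a measured 95% isodose area
#'
#' Bisection on `penumbra_sigma` until the standstill 95% isodose area
#' (referenced to the standstill maximum) matches `target95`.  This absorbs
#' the unknown true beam profile into a single measured quantity, e.g. the
#' 5.36 cm2 standstill area of the reference films.
#'
#' @param target95 target 95% isodose area in cm2, between 0 and the field
#'   area.
#' @param beam a [beam_model] whose `penumbra_sigma` is to be replaced.
#' @param spec a [dose_grid_spec] used for the pixel-counted area.
#' @param tol area tolerance in cm2 (default 0.01).
#' @return The calibrated [beam_model]; attribute `"achieved_area95"` holds
#'   the pixel-counted area actually reached.
#' @export
calibrate_penumbra <- function(target95, beam, spec = dose_grid_spec(),
                               tol = 0.01) {
  field_area <- beam$field_x * beam$field_y / 100  # cm2
  if (!is.finite(target95) || target95 <= 0 || target95 >= field_area) {
    stop("`target95` must lie strictly between 0 and the field area",
         call. = FALSE)
  }
  area_for <- function(sigma) {
    b <- beam
    b$penumbra_sigma <- sigma
    g <- static_dose(b, spec)
    isodose_area(g, 95, reference_max = max(g$dose))
  }
  lo <- 0.05
  hi <- min(beam$field_x, beam$field_y) / 2
  if (area_for(lo) < target95 || area_for(hi) > target95) {
    stop("calibration target not bracketable on the sigma interval",
         call. = FALSE)
  }
  best <- NULL
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    a <- area_for(mid)
    if (is.null(best) || abs(a - target95) < abs(best$a - target95)) {
      best <- list(sigma = mid, a = a)
    }
    if (abs(a - target95) <= tol && (hi - lo) < 1e-3) break
    if (a > target95) lo <- mid else hi <- mid
  }
  if (abs(best$a - target95) > tol) {
    stop(sprintf("calibration failed: best area %.4f cm2 vs target %.4f cm2",
                 best$a, target95), call. = FALSE)
  }
  out <- beam
  out$penumbra_sigma <- best$sigma
  attr(out, "achieved_area95") <- best$a
  out
}

#' Accumulate dose on a moving film
#'
#' Time-stepped dose accumulation for a film riding the motion stage: the
#' dose at film point `(x, y)` is the time integral of the static profile
#' sampled at `x - r(t)` (motion along the x/SI axis only),
#' `D(x, y) = dose_rate * sum_i Px(x - r(t_i)) * Py(y) * dt`.
#' With zero motion this reproduces `static_dose` scaled by
#' `duration * dose_rate / norm_dose`.
#'
#' @param beam a [beam_model].
#' @param film_motion residual film displacement [resp_trace]; must cover
#'   `[0, duration]`.
#' @param duration irradiation time in seconds (default 44.4 s).
#' @param spec a [dose_grid_spec].
#' @return A [dose_grid] of accumulated dose in cGy.
#' @export
accumulate_dose <- function(beam, film_motion, duration = 44.4,
                            spec = dose_grid_spec()) {
  stopifnot_trace(film_motion, kind = "displacement")
  if (diff(range(spec$x)) < beam$field_x ||
      diff(range(spec$y)) < beam$field_y) {
    stop("grid smaller than the field", call. = FALSE)
  }
  dt <- film_motion$dt
  if (film_motion$t0 > 1e-9 ||
      trace_duration(film_motion) + film_motion$t0 < duration - dt - 1e-9) {
    stop("film motion trace does not cover the irradiation window",
         call. = FALSE)
  }
  t <- trace_times(film_motion)
  keep <- t >= 0 & t < duration - 1e-12
  r <- film_motion$values[keep]
  # sum of shifted 1D profiles over time steps (separable beam)
  shifted <- outer(spec$x, r, "-")
  px_sum <- rowSums(beam_profile_1d(shifted, beam$field_x,
                                    beam$penumbra_sigma))
  py <- beam_profile_1d(spec$y, beam$field_y, beam$penumbra_sigma)
  dose_grid(beam$dose_rate * dt * outer(py, px_sum), spec)
}

#' Central-axis dose profile
#'
#' Extracts the central row (y = 0) of a dose grid on the film-axis
#' convention: position 0 mm is the couch side, 80 mm the gantry side and
#' 40 mm the film centre, so the nominal field spans 25--55 mm.
#'
#' @param grid a [dose_grid].
#' @param centre_position position of the film centre on the axis in mm.
#' @return A data frame with columns `position_mm` and `dose`.
#' @export
dose_profile <- function(grid, centre_position = 40) {
  if (!inherits(grid, "dose_grid")) {
    stop("`grid` must be a dose_grid", call. = FALSE)
  }
  row <- which.min(abs(grid$y))
  data.frame(position_mm = grid$x + centre_position,
             dose = grid$dose[row, ])
}

#' Read and write dose grids as delimited text with a JSON sidecar
#'
#' The grid is written as tab-separated values (rows = y, columns = x) plus
#' a `<path>.json` sidecar carrying `nx`, `ny`, `spacing_mm`, `origin_mm`
#' and `units`.  The reader validates the matrix shape against the sidecar.
#'
#' @param grid a [dose_grid].
#' @param path path of the delimited text file.
#' @return `read_dose_grid` returns a [dose_grid]; `write_dose_grid`
#'   invisibly returns `path`.
#' @export
write_dose_grid <- function(grid, path) {
  if (!inherits(grid, "dose_grid")) {
    stop("`grid` must be a dose_grid", call. = FALSE)
  }
  utils::write.table(format(grid$dose, digits = 10, trim = TRUE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  side <- list(nx = length(grid$x), ny = length(grid$y),
               spacing_mm = grid$spacing,
               origin_mm = c(grid$x[1], grid$y[1]), units = grid$units)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_dose_grid
#' @export
read_dose_grid <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                   colClasses = "numeric"))
  dimnames(m) <- NULL
  if (nrow(m) != side$ny || ncol(m) != side$nx) {
    stop(sprintf("grid shape %d x %d does not match sidecar %d x %d",
                 nrow(m), ncol(m), side$ny, side$nx), call. = FALSE)
  }
  spec <- list(x = side$origin_mm[1] + (seq_len(side$nx) - 1) * side$spacing_mm,
               y = side$origin_mm[2] + (seq_len(side$ny) - 1) * side$spacing_mm,
               spacing = side$spacing_mm)
  class(spec) <- "dose_grid_spec"
  dose_grid(m, spec, units = side$units)
}
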