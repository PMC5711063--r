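#' Fluoroscope projection geometry (similar triangles)
#'
#' The C-arm projection model: a point source, objects at distances `a`
#' (target, e.g. diaphragm apex) and `c` (calibration rod of the target
#' simulator) from the source, and the imaging plane at distance `e`.  An
#' in-plane object displacement `b` at distance `a` projects to an image
#' displacement `f` with `b / a = f / e` (and likewise `d / c = f / e` for
#' the rod), so two objects sharing one image displacement satisfy
#' `d / b = c / a`.
#'
#' @param a source-to-target distance in mm.
#' @param c source-to-rod distance in mm.
#' @param e source-to-imaging-plane distance in mm.  Both objects must lie
#'   between source and plane: `0 < a <= e`, `0 < c <= e`.
#' @return A `geometry_setup` list.
#' @export
geometry_setup <- function(a, c, e) {
  vals <- c(a = a, c = c, e = e)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("all distances must be positive and finite", call. = FALSE)
  }
  if (a > e || c > e) {
    stop("objects must lie between source and imaging plane (a, c <= e)",
         call. = FALSE)
  }
  structure(list(a = a, c = c, e = e), class = "geometry_setup")
}

check_dist <- function(dist, geo) {
  if (!is.finite(dist) || dist <= 0 || dist > geo$e) {
    stop("object distance must satisfy 0 < dist <= e", call. = FALSE)
  }
}

#' Project / back-project in-plane displacements through the C-arm geometry
#'
#' `project()` maps a true object displacement at source distance `dist` to
#' its image-plane displacement `f = true_disp * e / dist`; `backproject()`
#' inverts it.  Displacements are treated as small in-plane translations, so
#' the similar-triangle magnification is exact.
#'
#' @param true_disp true object displacement in mm.
#' @param f projected image displacement in mm.
#' @param dist source-to-object distance in mm, `0 < dist <= e`.
#' @param geo a [geometry_setup].
#' @return Displacement in mm.
#' @examples
#' geo <- geometry_setup(a = 800, c = 600, e = 1000)
#' project(7.3, dist = 800, geo)      # 9.125
#' backproject(9.125, dist = 800, geo)
#' @export
project <- function(true_disp, dist, geo) {
  check_dist(dist, geo)
  true_disp * geo$e / dist
}

#' @rdname project
#' @export
backproject <- function(f, dist, geo) {
  check_dist(dist, geo)
  f * dist / geo$e
}

#' Rod-to-target displacement ratio
#'
#' The ratio `d / b = c / a` between the displacement of the calibration rod
#' and that of the target when both project onto the same image
#' displacement.  Observed rod displacements divided by this ratio recover
#' the target displacement, which is what the compensation stage consumes.
#'
#' @param geo a [geometry_setup].
#' @return The dimensionless ratio `c / a`.
#' @export
rod_to_target_ratio <- function(geo) {
  if (!inherits(geo, "geometry_setup")) {
    stop("`geo` must be a geometry_setup", call. = FALSE)
  }
  geo$c / geo$a
}

#' Affine surrogate calibration (gain and shift)
#'
#' Least-squares fit of `target ~ gain * surrogate + shift`, standing in for
#' the manual gain/offset adjustment performed under fluoroscopy until the
#' surrogate-driven simulator tracks the target.  The shift aligns the
#' baseline position only; velocity-like quantities scale with the gain.
#'
#' @param surrogate surrogate [resp_trace] (voltage or displacement).
#' @param target target displacement [resp_trace]; must share length and
#'   sampling interval with `surrogate`.
#' @return An `affine_cal` list with fields `gain` (mm/V or dimensionless),
#'   `shift` (mm) and `residual_rms` (mm).
#' @export
fit_affine <- function(surrogate, target) {
  stopifnot_trace(surrogate)
  stopifnot_trace(target, kind = "displacement")
  if (length(surrogate$values) != length(target$values)) {
    stop("surrogate and target must have equal length", call. = FALSE)
  }
  if (abs(surrogate$dt - target$dt) > 1e-9 * target$dt) {
    stop("surrogate and target must share the sampling interval",
         call. = FALSE)
  }
  s <- surrogate$values
  x <- target$values
  if (stats::sd(s) == 0) {
    stop("degenerate fit: surrogate has zero variance", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, s), x)
  structure(list(gain = unname(fit$coefficients[2]),
                 shift = unname(fit$coefficients[1]),
                 residual_rms = sqrt(mean(fit$residuals^2))),
            class = "affine_cal")
}

#' Apply an affine calibration to a surrogate trace
#'
#' @param cal an `affine_cal` from [fit_affine()].
#' @param surrogate the surrogate [resp_trace].
#' @return A displacement [resp_trace] `gain * surrogate + shift`.
#' @export
apply_cal <- function(cal, surrogate) {
  if (!inherits(cal, "affine_cal")) {
    stop("`cal` must be an affine_cal", call. = FALSE)
  }
  stopifnot_trace(surrogate)
  resp_trace(cal$gain * surrogate$values + cal$shift,
             dt = surrogate$dt, t0 = surrogate$t0, kind = "displacement")
}
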