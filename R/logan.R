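# Logan graphical analysis: total distribution volume (VT) from a tissue
# curve and an input function, per region or per voxel.
#
# For a reversible tracer, after an equilibration time t*, the points
#   x(T) = int_0^T Cp dt / C_T(T),   y(T) = int_0^T C_T dt / C_T(T)
# fall on a line whose slope is VT. The fit is ordinary least squares over
# frames with midpoint >= t*.

#' Logan fit configuration
#'
#' @param t_star_s Start of the linear fit window in seconds (default 900,
#'   i.e. the late linear segment of a 60-min scan).
#' @param min_points Minimum number of fit points (default 4).
#' @return An object of class `logan_config`.
#' @export
logan_config <- function(t_star_s = 900, min_points = 4L) {
  if (t_star_s < 0) .stop_validation("t_star_s must be >= 0")
  if (min_points < 2L) .stop_validation("min_points must be >= 2")
  structure(list(t_star_s = t_star_s, min_points = as.integer(min_points)),
            class = "logan_config")
}

#' Cumulative trapezoidal integral
#'
#' @param times_s Strictly increasing sample times.
#' @param values Sampled values.
#' @param anchor Prepend a `(0, 0)` anchor when the first time is positive,
#'   so integrals start at injection (default `TRUE`).
#' @return Running integral evaluated at `times_s`.
#' @export
cumtrapz <- function(times_s, values, anchor = TRUE) {
  n <- length(times_s)
  if (n < 2L) .stop_validation("cumtrapz needs at least 2 samples")
  if (length(values) != n) .stop_validation("times and values differ in length")
  if (any(diff(times_s) <= 0))
    .stop_validation("times must be strictly increasing")
  if (anchor && times_s[1] > 0) {
    times_s <- c(0, times_s)
    values <- c(0, values)
    drop_first <- TRUE
  } else drop_first <- FALSE
  inc <- c(0, diff(times_s) * (values[-1] + values[-length(values)]) / 2)
  out <- cumsum(inc)
  if (drop_first) out[-1] else out
}

#' Construct an input function
#'
#' @param times_s Strictly increasing sample times (typically frame
#'   midpoints).
#' @param values Activity values, same units as the image.
#' @param source `"idif"` or `"true_aif"`.
#' @return An object of class `input_function`.
#' @export
input_function <- function(times_s, values, source = c("idif", "true_aif")) {
  source <- match.arg(source)
  if (any(diff(times_s) <= 0))
    .stop_validation("input function times must be strictly increasing")
  if (any(!is.finite(values)))
    .stop_validation("non-finite input function values")
  structure(list(times_s = as.numeric(times_s), values = as.numeric(values),
                 source = source),
            class = "input_function")
}

#' @export
print.input_function <- function(x, ...) {
  cat(sprintf("input_function (%s): %d samples, peak %.3g at %g s\n",
              x$source, length(x$times_s), max(x$values),
              x$times_s[which.max(x$values)]))
  invisible(x)
}

.resample_input <- function(input, times_s) {
  if (length(input$times_s) == length(times_s) &&
      all(abs(input$times_s - times_s) < 1e-9)) return(input$values)
  stats::approx(input$times_s, input$values, xout = times_s,
                yleft = 0, rule = 2)$y
}

#' Logan fit for one tissue curve
#'
#' @param tissue_values Tissue activity per frame.
#' @param times_s Frame midpoints.
#' @param input An [input_function()]; resampled to `times_s` by linear
#'   interpolation if on a different grid.
#' @param cfg A [logan_config()].
#' @return An object of class `logan_fit` with fields `slope` (VT),
#'   `intercept`, `r2`, `n_points`.
#' @export
logan_fit <- function(tissue_values, times_s, input, cfg = logan_config()) {
  stopifnot(inherits(input, "input_function"), inherits(cfg, "logan_config"))
  if (length(tissue_values) != length(times_s))
    .stop_validation("tissue values and times differ in length")
  cp <- .resample_input(input, times_s)
  int_cp <- cumtrapz(times_s, cp)
  int_ct <- cumtrapz(times_s, tissue_values)
  sel <- which(times_s >= cfg$t_star_s)
  bad <- sel[tissue_values[sel] <= 0]
  if (length(bad)) {
    warning("petref: dropped ", length(bad),
            " fit point(s) with nonpositive tissue activity", call. = FALSE)
    sel <- setdiff(sel, bad)
  }
  if (length(sel) < cfg$min_points)
    .stop_validation("fewer than min_points (", cfg$min_points,
                     ") usable Logan fit points")
  x <- int_cp[sel] / tissue_values[sel]
  y <- int_ct[sel] / tissue_values[sel]
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- unname(fit$coefficients[2])
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  structure(list(slope = slope, intercept = unname(fit$coefficients[1]),
                 r2 = r2, n_points = length(sel),
                 t_star_s = cfg$t_star_s),
            class = "logan_fit")
}

#' @export
print.logan_fit <- function(x, ...) {
  cat(sprintf("logan_fit: VT = %.4g (intercept %.3g, R2 %.4f, %d points, t* = %g s)\n",
              x$slope, x$intercept, x$r2, x$n_points, x$t_star_s))
  invisible(x)
}

#' Voxel-wise Logan VT map
#'
#' Vectorized Logan fit at every voxel of a brain mask. Voxels whose fit
#' fails (nonpositive late activity, degenerate abscissa) are set to `NA`
#' and counted; more than 50% failures aborts.
#'
#' @param img A [dynamic_image()].
#' @param input An [input_function()].
#' @param cfg A [logan_config()].
#' @param brain_mask Logical 3D array of voxels to fit.
#' @return A [static_image()] with quantity `"VT"`; attribute `n_failed`
#'   carries the failed-voxel count.
#' @export
vt_map <- function(img, input, cfg = logan_config(), brain_mask) {
  stopifnot(inherits(img, "dynamic_image"))
  if (!any(brain_mask)) .stop_validation("brain_mask is empty")
  times <- img$schedule$mid_s
  cp <- .resample_input(input, times)
  int_cp <- cumtrapz(times, cp)
  d <- dim(img$voxels)
  vmat <- matrix(img$voxels, prod(d[1:3]), d[4])[which(brain_mask), , drop = FALSE]
  nfrm <- d[4]
  # cumulative trapezoid with injection anchor, per voxel (rows)
  tprev <- c(0, times[-nfrm])
  wid <- times - tprev
  prev <- cbind(0, vmat[, -nfrm, drop = FALSE])
  int_ct <- t(apply(sweep((vmat + prev) / 2, 2, wid, `*`), 1, cumsum))
  sel <- which(times >= cfg$t_star_s)
  if (length(sel) < cfg$min_points)
    .stop_validation("fewer than min_points frames at or after t*")
  ct <- vmat[, sel, drop = FALSE]
  ok <- rowSums(ct <= 0) == 0
  x <- sweep(1 / ct, 2, int_cp[sel], `*`)
  y <- int_ct[, sel, drop = FALSE] / ct
  n <- length(sel)
  sx <- rowSums(x); sy <- rowSums(y)
  sxx <- rowSums(x * x); sxy <- rowSums(x * y)
  denom <- sxx - sx^2 / n
  slope <- (sxy - sx * sy / n) / denom
  ok <- ok & is.finite(slope) & denom > 0
  slope[!ok] <- NA_real_
  n_failed <- sum(!ok)
  if (n_failed > 0.5 * length(slope))
    stop("petref: Logan fit failed in >50% of voxels")
  vol <- array(NA_real_, d[1:3])
  vol[which(brain_mask)] <- slope
  out <- static_image(vol, img$spacing_mm, "VT")
  attr(out, "n_failed") <- n_failed
  out
}
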