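#' Fit the response centerline by AIC-selected polynomial regression
#'
#' Least-squares polynomial fits of the masked response voxels, with the
#' order chosen by the Akaike information criterion
#' `AIC = n * log(RSS / n) + 2 * (order + 2)`. Selection walks up from
#' order 1 and advances only while the next order improves the AIC by at
#' least `delta` (default 2): orders within `delta` of each other are ties
#' resolved toward the smaller order, and the walk stops at the first
#' non-significant drop, guarding against spurious high-order wiggles.
#'
#' The independent axis is the one with the larger coordinate spread (for a
#' near-vertical band in the chosen parameterization the axes are swapped
#' and the fit flagged `swapped`).
#'
#' @param points Two-column matrix or data frame of mask coordinates
#'   `(x, y)` in mm (the centerline is modelled as `x = f(y)`).
#' @param max_order Largest candidate order (default 5; reduced when there
#'   are too few points).
#' @param delta AIC tie margin, default 2.
#' @param weights Optional non-negative observation weights (e.g. response
#'   amplitudes, to pull the fit onto the response ridge).
#' @return An object of class `centerline_fit`: `coef` (ascending
#'   polynomial coefficients of `x = f(y)`), `order`, `aic` (per candidate
#'   order), `rss`, `swapped`, `n`.
#' @export
fit_centerline <- function(points, max_order = 5, delta = 2, weights = NULL) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2) stop("fit_centerline: points must have two columns", call. = FALSE)
  keep <- stats::complete.cases(pts)
  pts <- pts[keep, , drop = FALSE]
  if (!is.null(weights)) weights <- weights[keep]
  n <- nrow(pts)
  max_order <- min(max_order, n - 2)
  if (max_order < 1)
    stop("fit_centerline: need at least max_order + 2 points", call. = FALSE)
  xv <- pts[, 1]; yv <- pts[, 2]
  swapped <- FALSE
  if (stats::sd(yv) < stats::sd(xv)) {
    # near-horizontal band in the (x = f(y)) parameterization: swap axes
    tmp <- xv; xv <- yv; yv <- tmp
    swapped <- TRUE
    message("fit_centerline: independent axis swapped (near-degenerate geometry)")
  }
  orders <- 1:max_order
  fits <- lapply(orders, function(k)
    stats::lm(xv ~ stats::poly(yv, k, raw = TRUE), weights = weights))
  rss <- vapply(fits, function(f) sum(stats::resid(f)^2 *
                                        (if (is.null(weights)) 1 else weights)), 1)
  # numerically exact fits leave only rounding noise in the residual; floor
  # the RSS at that level so the AIC penalty, not log(eps), decides
  rss_floor <- n * (1e-9 * max(stats::sd(xv), 1e-9))^2
  aic <- n * log(pmax(rss, rss_floor) / n) + 2 * (orders + 2)
  # advance while the drop to the next order is significant
  order <- 1L
  while (order < max_order && aic[order + 1] <= aic[order] - delta)
    order <- order + 1L
  cf <- unname(stats::coef(fits[[which(orders == order)]]))
  structure(list(coef = cf, order = order, aic = aic, orders = orders,
                 rss = rss, swapped = swapped, n = n),
            class = "centerline_fit")
}

#' @export
print.centerline_fit <- function(x, ...) {
  cat(sprintf("<centerline_fit> order %d (AIC %.1f)%s; coef: %s\n", x$order,
              x$aic[x$order], if (x$swapped) " [axes swapped]" else "",
              paste(signif(x$coef, 4), collapse = ", ")))
  invisible(x)
}

#' Isoeccentric (along-line) averaging
#'
#' Collapses the flat map onto the coordinate perpendicular to the
#' centerline: every voxel is assigned its signed perpendicular distance
#' `x` to the fitted centerline (positive toward the configured side, the
#' foveal analogue), responses are binned at the voxel pitch out to
#' `x_max`, and averaged at each time point. Bins containing no voxels are
#' returned as missing (`NA`), not zero.
#'
#' @param ds A [make_flatmap_dataset()]-style dataset; `y` may have been
#'   filtered beforehand.
#' @param centerline A [fit_centerline()] object, or ascending polynomial
#'   coefficients of `x = f(y)`.
#' @param x_max Maximum |distance| (mm), default 10.
#' @param positive `"+x"` (default) if the positive map direction is the
#'   positive side, else `"-x"`.
#' @return An object of class `avg_response`: matrix `y` (bins x time),
#'   `x` bin centers, `t`, `counts`, `missing`.
#' @export
isoeccentric_average <- function(ds, centerline, x_max = 10, positive = c("+x", "-x")) {
  positive <- match.arg(positive)
  cf <- if (inherits(centerline, "centerline_fit")) centerline$coef
        else as.numeric(centerline)
  xc_rng <- range(polyval_asc(cf, ds$yrow))
  if (xc_rng[1] < min(ds$x) || xc_rng[2] > max(ds$x))
    stop("isoeccentric_average: centerline lies outside the data extent", call. = FALSE)
  dmat <- signed_curve_distance(ds$x, ds$yrow, cf)
  if (positive == "-x") dmat <- -dmat
  nb <- floor(x_max / ds$pitch)
  bins <- seq(-nb * ds$pitch, nb * ds$pitch, by = ds$pitch)  # bin on x = 0
  ib <- round(dmat / ds$pitch) + nb + 1L
  ok <- ib >= 1L & ib <= length(bins) & abs(dmat) <= x_max + ds$pitch / 2
  d <- dim(ds$y)
  mat <- matrix(ds$y, d[1] * d[2], d[3])
  idx <- as.vector(ib)[as.vector(ok)]
  sel <- which(as.vector(ok))
  counts <- tabulate(idx, nbins = length(bins))
  acc <- matrix(0, length(bins), d[3])
  acc <- rowsum(mat[sel, , drop = FALSE], group = idx)
  ybar <- matrix(NA_real_, length(bins), d[3])
  got <- sort(unique(idx))
  ybar[got, ] <- acc / counts[got]
  structure(list(y = ybar, x = bins, t = ds$t, counts = counts,
                 missing = counts == 0),
            class = "avg_response")
}
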