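#' Plot an instantaneous-phase field
#'
#' Image of the instantaneous phase over perpendicular distance and epoch
#' time, with the amplitude mask applied (masked positions blank).
#'
#' @param x A [analytic_phase()] result.
#' @param ... Passed to [graphics::image()].
#' @export
plot.phase_field <- function(x, ...) {
  phi <- x$phi
  graphics::image(x$t, x$x, t(phi), col = grDevices::hcl.colors(64, "Cyan-Magenta"),
                  xlab = "time since block onset (s)",
                  ylab = "distance from centerline (mm)",
                  main = "instantaneous phase (rad)", ...)
  invisible(x)
}

#' Plot recovered wave estimates
#'
#' Image of the averaged spatiotemporal response `y(x, t)` with the
#' extracted phase-front points overlaid (foveal side up, peripheral side
#' down), the standard way to display a traveling-wave fit.
#'
#' @param x A [recover_parameters()] result.
#' @param ... Passed to [graphics::image()].
#' @export
plot.wave_estimates <- function(x, ...) {
  avg <- attr(x, "avg")
  fronts <- attr(x, "fronts")
  fold <- attr(x, "phase")
  y <- fold$env * cos(fold$phi)          # filtered epoch reconstruction
  graphics::image(fold$t, fold$x, t(y),
                  col = grDevices::hcl.colors(64, "Blue-Red 3"),
                  xlab = "time since block onset (s)",
                  ylab = "distance from centerline (mm)",
                  main = "averaged response with phase fronts", ...)
  for (side in c("F", "P")) {
    f <- fronts[[side]]
    if (is.null(f$flag))
      graphics::points(f$t, if (side == "F") f$x else -f$x, pch = 19,
                       col = if (side == "F") "red" else "black")
  }
  invisible(x)
}

#' Plot a parameter-sweep gallery
#'
#' One `y(x, t)` panel per `(v_beta, Gamma)` pair, arranged with speed
#' along columns and damping along rows.
#'
#' @param x A [parameter_sweep()] result.
#' @param ... Passed to [graphics::image()].
#' @export
plot.wave_sweep <- function(x, ...) {
  s <- x$summary
  vs <- sort(unique(s$v_beta)); gs <- sort(unique(s$Gamma))
  op <- graphics::par(mfrow = c(length(gs), length(vs)),
                      mar = c(2, 2, 1.5, 0.5))
  on.exit(graphics::par(op))
  g <- x$grid
  for (gg in gs) for (vv in vs) {
    i <- which(s$v_beta == vv & s$Gamma == gg)
    yv <- x$fields[[i]]$values
    if (g$ny > 1L) yv <- yv[, grid_origin(g)["iy"], ]
    graphics::image(g$t, g$x, t(yv),
                    col = grDevices::hcl.colors(64, "Blue-Red 3"),
                    main = sprintf("v=%g, G=%g", vv, gg), ...)
  }
  invisible(x)
}
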