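#' Quick-look plots
#'
#' Base-graphics helpers: `plotRaster` draws a spike raster (one row per
#' neuron or electrode), `plotParticipation` the number of electrodes
#' bursting at each time point.
#'
#' @param x a [SimulationResult-class] or [MEARecording-class] (for
#'   `plotRaster`), or a [ParticipationTrace-class] (for
#'   `plotParticipation`).
#' @param ... passed to [graphics::plot()].
#' @return `NULL`, invisibly.
#' @name quick-plots
NULL

#' @rdname quick-plots
#' @export
plotRaster <- function(x, ...) {
  if (is(x, "SimulationResult")) {
    graphics::plot(x@raster$time, x@raster$neuron, pch = ".",
                   xlab = "time (s)", ylab = "neuron", ...)
  } else if (is(x, "MEARecording")) {
    ids <- electrodeIds(x)
    graphics::plot(NA, xlim = c(0, x@duration), ylim = c(0, length(ids) + 1),
                   xlab = "time (s)", ylab = "electrode", yaxt = "n", ...)
    graphics::axis(2, at = seq_along(ids), labels = ids, las = 1,
                   cex.axis = 0.5)
    for (k in seq_along(ids))
      graphics::points(x@spikes[[k]], rep(k, length(x@spikes[[k]])),
                       pch = ".")
  } else stop("plotRaster needs a SimulationResult or MEARecording")
  invisible(NULL)
}

#' @rdname quick-plots
#' @export
plotParticipation <- function(x, ...) {
  stopifnot(is(x, "ParticipationTrace"))
  mid <- (seq_along(x@counts) - 0.5) * x@binWidth
  graphics::plot(mid, x@counts, type = "s", xlab = "time (s)",
                 ylab = "electrodes bursting", ...)
  invisible(NULL)
}
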