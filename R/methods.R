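#' @export
print.lv_sim <- function(x, ...) {
  nc <- nrow(x$work)
  cat(sprintf("LV simulation: %d cardiac cycle(s), %d accepted steps\n",
              nc, nrow(x$time)))
  w <- x$work[nc, ]
  cat(sprintf("  final cycle: stroke work %.3f J, internal %.3f J (fiber %.3f, viscous %.3f)\n",
              w$stroke, w$internal, w$fiber, w$viscous))
  cat(sprintf("  LV volume range %.1f-%.1f cm^3, peak pressure %.2f kPa\n",
              min(x$time$V), max(x$time$V), max(x$time$p)))
  invisible(x)
}

#' Summary of a cardiac-cycle simulation
#'
#' Converged-cycle averages of the work ledger, stroke volume, ejection
#' fraction, peak pressures, and cycle-to-cycle periodicity drift.
#'
#' @param object an \code{lv_sim} object.
#' @param converged which cycles count as converged (default: second half).
#' @param ... unused.
#' @return An object of class \code{"summary.lv_sim"}.
#' @export
summary.lv_sim <- function(object, converged = NULL, ...) {
  w <- object$work
  nc <- nrow(w)
  if (is.null(converged)) converged <- seq(max(1, nc %/% 2), nc)
  wc <- w[w$cycle %in% converged, ]
  tm <- object$time
  last <- tm[tm$t > (nc - 1) * object$model$material$T_c - 1e-9, ]
  drift <- if (nc >= 2) abs(w$stroke[nc] - w$stroke[nc - 1]) /
    abs(w$stroke[nc]) else NA
  out <- list(
    cycles = nc, converged = converged,
    work = colMeans(wc[, c("fiber", "viscous", "elastic", "internal",
                           "external", "stroke")]),
    closure = max(wc$closure),
    stroke_volume = max(last$V) - min(last$V),
    EDV = max(last$V), ESV = min(last$V),
    peak_p = max(last$p), peak_P_AO = max(last$P_AO),
    stroke_drift = drift,
    V_loop_gap = abs(w$V_end[nc] - w$V_start[nc]) / w$V_start[nc])
  class(out) <- "summary.lv_sim"
  out
}

#' @export
print.summary.lv_sim <- function(x, ...) {
  cat(sprintf("LV simulation over %d cycles (averages over cycles %d-%d)\n",
              x$cycles, min(x$converged), max(x$converged)))
  cat(sprintf("  stroke work %.3f J/cycle; internal %.3f = fiber %.3f + viscous %.3f + elastic %.4f\n",
              x$work["stroke"], x$work["internal"], x$work["fiber"],
              x$work["viscous"], x$work["elastic"]))
  cat(sprintf("  |internal - stroke|/stroke: %.3f%%\n", 100 * x$closure))
  cat(sprintf("  EDV %.1f, ESV %.1f, stroke volume %.1f cm^3 (EF %.0f%%)\n",
              x$EDV, x$ESV, x$stroke_volume, 100 * x$stroke_volume / x$EDV))
  cat(sprintf("  peak LV pressure %.2f kPa; cycle-to-cycle stroke-work drift %.4f%%\n",
              x$peak_p, 100 * x$stroke_drift))
  invisible(x)
}

#' Plot a cardiac-cycle simulation
#'
#' @param x an \code{lv_sim} object.
#' @param which \code{"pv"} for the pressure-volume loop, \code{"time"}
#'   for time courses of pressures and volume.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, \code{x}.
#' @export
plot.lv_sim <- function(x, which = c("pv", "time"), ...) {
  which <- match.arg(which)
  tm <- x$time
  if (which == "pv") {
    graphics::plot(tm$V, tm$p, type = "l", xlab = expression(V ~ (cm^3)),
                   ylab = "p (kPa)", main = "LV pressure-volume loop", ...)
  } else {
    graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
    graphics::plot(tm$t, tm$p, type = "l", xlab = "t (s)", ylab = "kPa", ...)
    graphics::lines(tm$t, tm$P_AO, lty = 2)
    graphics::lines(tm$t, tm$P_A, lty = 3)
    graphics::legend("topright", c("p", "P_AO", "P_A"), lty = 1:3, bty = "n")
    graphics::plot(tm$t, tm$V, type = "l", xlab = "t (s)",
                   ylab = expression(V ~ (cm^3)))
  }
  invisible(x)
}

#' Residuals of the algebraic constraints along a simulation
#'
#' Recomputes the flow-balance constraint residual at each recorded step
#' (mitral inflow minus aortic outflow minus rate of volume change must
#' vanish at the converged per-stage solution).
#'
#' @param object an \code{lv_sim} object.
#' @param ... unused.
#' @return Numeric vector of residuals (cm^3/s), one per recorded step.
#' @export
residuals.lv_sim <- function(object, ...) {
  tm <- object$time
  tm$dVdt - tm$q_mv + tm$q_ao
}
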