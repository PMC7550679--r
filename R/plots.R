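#' Plot a simulation trace
#'
#' Line panels of unit activations over time (base graphics), one panel per
#' unit group, in the style of a session-course figure; CS/US epochs are
#' shaded.
#'
#' @param x A `fear_trace`.
#' @param units Units to draw (default: all, grouped by region prefix).
#' @param ... Passed to `matplot`.
#' @return `x`, invisibly.
#' @export
plot.fear_trace <- function(x, units = colnames(x$A), ...) {
  groups <- split(units, sub("^(LA|BA|Ce|ITC|PL|IL).*", "\\1", units))
  old <- graphics::par(mfrow = c(length(groups), 1),
                       mar = c(2, 4, 1, 1))
  on.exit(graphics::par(old))
  ep <- x$protocol$epochs
  for (g in names(groups)) {
    us <- groups[[g]]
    graphics::matplot(x$time_s, x$A[, us, drop = FALSE], type = "l",
                      lty = 1, xlab = "", ylab = paste0(g, " (Hz)"), ...)
    if (nrow(ep)) {
      cs <- ep[ep$channel == "CS", ]
      if (nrow(cs))
        graphics::rect(cs$t_start, -1, cs$t_start + cs$duration, 0,
                       col = grDevices::grey(0.8), border = NA)
      us_ep <- ep[ep$channel == "US", ]
      if (nrow(us_ep))
        graphics::rect(us_ep$t_start, -1,
                       us_ep$t_start + us_ep$duration, 0,
                       col = "black", border = NA)
    }
    graphics::legend("topright", legend = us, col = seq_along(us),
                     lty = 1, bty = "n", cex = 0.7)
  }
  invisible(x)
}
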