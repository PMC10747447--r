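#' Overlay plot of an aligned trace pair
#'
#' Plots both systems' angle traces on the 0--99 normalised frame grid:
#' the markerless test trace in red, the reference trace in black, matching
#' the conventional presentation of concurrent-validity comparisons.
#'
#' @param pair an `aligned_pair` (see [pair_traces()]).
#' @param main plot title.
#' @param ... further arguments passed to [graphics::matplot()].
#' @return Invisibly, `pair`.
#' @export
plot_aligned_pair <- function(pair, main = NULL, ...) {
  stopifnot(inherits(pair, "aligned_pair"))
  idx <- seq_along(pair$test) - 1L
  main <- main %||% sprintf("%s (n = %d frames)", pair$task, length(idx))
  graphics::matplot(idx, cbind(pair$reference, pair$test), type = "l",
                    lty = 1, lwd = 2, col = c("black", "red"),
                    xlab = "normalised frame", ylab = "angle (deg)",
                    main = main, ...)
  graphics::legend("topright", legend = c("reference", "markerless"),
                   col = c("black", "red"), lty = 1, lwd = 2, bty = "n")
  invisible(pair)
}
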