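# Base-graphics figures: Kaplan-Meier curves and an SMD love plot.

#' @export
#' @importFrom graphics lines legend abline points axis par
plot.km_curve <- function(x, col = c("black", "grey40"),
                          xlab = "Years since surgery",
                          ylab = "Overall survival", ...) {
  xmax <- max(unlist(lapply(x, `[[`, "time")))
  plot(NA, xlim = c(0, xmax), ylim = c(0, 1), xlab = xlab, ylab = ylab, ...)
  for (i in seq_along(x))
    lines(c(0, x[[i]]$time), c(1, x[[i]]$surv), type = "s",
          col = col[(i - 1) %% length(col) + 1], lwd = 2)
  legend("topright", legend = names(x), col = col[seq_along(x)],
         lwd = 2, bty = "n")
  invisible(x)
}

#' @export
plot.balance_table <- function(x, threshold = 0.1, ...) {
  ord <- order(x$smd_unweighted)
  n <- nrow(x)
  plot(NA, xlim = c(0, max(x$smd_unweighted, x$smd_weighted, threshold)),
       ylim = c(0.5, n + 0.5), yaxt = "n",
       xlab = "Absolute standardized mean difference", ylab = "", ...)
  axis(2, at = seq_len(n), labels = x$covariate[ord], las = 1,
       cex.axis = 0.7)
  points(x$smd_unweighted[ord], seq_len(n), pch = 1)
  points(x$smd_weighted[ord], seq_len(n), pch = 16)
  abline(v = threshold, lty = 2)
  legend("bottomright", legend = c("unweighted", "weighted"),
         pch = c(1, 16), bty = "n")
  invisible(x)
}
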