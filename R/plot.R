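#' Render a conditioning plot
#'
#' Draws the classic two-panel conditioning plot: an upper panel of
#' overlapping disease-load interval bars and a row of lower scatterplots
#' of performance against the fMRI feature for the subjects in each
#' interval, each with its display regression line. Intervals run from
#' smallest volume (highest structural disease load, leftmost) to largest.
#'
#' @param x a `coplot_spec` from [coplot_intervals()].
#' @param d,f,y the data vectors the interval specification was built from.
#' @param xlab,ylab axis labels for the scatterplots.
#' @param dlab label for the conditioning variable.
#' @param ... ignored.
#' @return invisibly, `x`.
#' @export
plot.coplot_spec <- function(x, d, f, y, xlab = "fMRI signal",
                             ylab = "performance",
                             dlab = "volume fraction (low = high load)",
                             ...) {
  k <- x$k
  iv <- x$intervals
  op <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(op))
  graphics::layout(rbind(rep(1, k), 1 + seq_len(k)), heights = c(1, 2.4))
  cols <- grDevices::hcl.colors(k, "Zissou 1")
  # upper panel: interval slabs
  graphics::par(mar = c(2.5, 4, 1, 1))
  graphics::plot(range(d), c(0.5, k + 0.5), type = "n", yaxt = "n",
                 xlab = dlab, ylab = "interval")
  for (j in seq_len(k))
    graphics::rect(iv$lower[j], j - 0.35, iv$upper[j], j + 0.35,
                   col = grDevices::adjustcolor(cols[j], 0.6),
                   border = cols[j])
  # lower panels: per-interval scatter with display fit
  ylim <- range(y); xlim <- range(f)
  for (j in seq_len(k)) {
    sel <- x$indices[[j]]
    graphics::par(mar = c(4, if (j == 1) 4 else 2, 1, 0.5))
    graphics::plot(f[sel], y[sel], pch = 19, col = cols[j],
                   xlim = xlim, ylim = ylim, xlab = xlab,
                   ylab = if (j == 1) ylab else "")
    if (!is.na(iv$slope[j]))
      graphics::abline(iv$intercept[j], iv$slope[j], col = cols[j], lwd = 2)
  }
  invisible(x)
}
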