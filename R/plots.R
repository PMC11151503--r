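#' Phasor plot
#'
#' Draws phasor points over the universal semicircle
#' `(g - 1/2)^2 + s^2 = 1/4`, on which all mono-exponential decays fall;
#' mixtures fall inside it.
#'
#' @param points a `phasor_set` or data frame with `g`, `s` columns.
#' @param ... passed to [graphics::points()].
#' @export
phasor_plot <- function(points, ...) {
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 0.6), xlab = "g", ylab = "s",
                 main = "Phasor plot", asp = 1)
  th <- seq(0, pi, length.out = 200)
  graphics::lines(0.5 + 0.5 * cos(th), 0.5 * sin(th), col = "grey50")
  graphics::points(points$g, points$s, pch = 19, ...)
  invisible(points)
}

# Diagnostic figures for a study bundle (PDF device: headless-safe).
write_study_figures <- function(res, out_dir) {
  grDevices::pdf(file.path(out_dir, "figures.pdf"), width = 7, height = 5)
  on.exit(grDevices::dev.off())
  conds <- unique(res$orr$condition)
  # ORR histograms per condition
  graphics::par(mfrow = c(1, 2))
  for (cond in conds) {
    graphics::hist(res$orr$mean_orr[res$orr$condition == cond],
                   main = paste("per-cell ORR,", cond), xlab = "ORR",
                   xlim = c(0, 1), col = "grey80", breaks = 10)
  }
  # bar charts with SEM error bars per metric
  graphics::par(mfrow = c(2, 3))
  for (metric in unique(res$summaries$metric)) {
    s <- res$summaries[res$summaries$metric == metric, ]
    bp <- graphics::barplot(s$mean, names.arg = s$condition, main = metric,
                            ylim = c(0, max(s$mean + 2 * s$sem, na.rm = TRUE)))
    graphics::arrows(bp, s$mean - s$sem, bp, s$mean + s$sem,
                     angle = 90, code = 3, length = 0.05)
  }
  invisible(NULL)
}
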