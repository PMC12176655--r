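#' Plot a lineage forest as a time-versus-lineage diagram
#'
#' Draws each track as a horizontal segment over its observed time span,
#' stacked by tree, with vertical connectors at divisions — the standard
#' lineage-tree rendering of multigeneration tracking experiments.
#'
#' @param x a `lineage_forest`.
#' @param frame_interval minutes per frame for the time axis.
#' @param col_by colour tracks by "generation" (default) or a single colour.
#' @param ... passed to [graphics::plot()].
#' @export
plot.lineage_forest <- function(x, frame_interval = 30,
                                col_by = "generation", ...) {
  meta <- x$meta
  h <- frame_interval / 60
  # leaf order within each tree for a planar layout
  ypos <- rep(NA_real_, nrow(meta))
  names(ypos) <- meta$track
  y_next <- 0
  kids_of <- function(tr) {
    k <- x$divisions[x$divisions$parent == tr, c("daughter1", "daughter2")]
    if (!nrow(k)) integer(0) else
      stats::na.omit(c(k$daughter1[1], k$daughter2[1]))
  }
  assign_y <- function(tr) {
    ch <- kids_of(tr)
    if (!length(ch)) {
      y_next <<- y_next + 1
      ypos[as.character(tr)] <<- y_next
    } else {
      for (d in ch) assign_y(d)
      ypos[as.character(tr)] <<- mean(ypos[as.character(ch)])
    }
  }
  for (r in meta$track[is.na(meta$parent)]) assign_y(r)
  gens <- sort(unique(meta$generation))
  pal <- stats::setNames(grDevices::hcl.colors(max(3, length(gens)),
                                               "Dark 3")[seq_along(gens)],
                         gens)
  cols <- if (identical(col_by, "generation")) pal[meta$generation]
  else rep(col_by, nrow(meta))
  graphics::plot(NA, xlim = range(x$frames) * h,
                 ylim = c(0, y_next + 1), xlab = "time (h)",
                 ylab = "lineage", yaxt = "n", ...)
  graphics::segments(meta$start_frame * h, ypos[as.character(meta$track)],
                     meta$end_frame * h, ypos[as.character(meta$track)],
                     col = cols, lwd = 2)
  for (k in seq_len(nrow(x$divisions))) {
    d <- x$divisions[k, ]
    ys <- ypos[as.character(c(d$daughter1, d$daughter2))]
    graphics::segments(d$parent_end_frame * h, min(ys),
                       d$parent_end_frame * h, max(ys),
                       col = "grey40", lty = 3)
  }
  graphics::legend("topright", legend = gens, col = pal[gens], lwd = 2,
                   bty = "n", cex = 0.8)
  invisible(x)
}

#' Plot the mean-variance fit of a highly-variable-gene analysis
#'
#' Scatter of log2 s.d. against log2 mean per gene with the fitted line
#' and the residual cutoff band; highly variable genes are highlighted.
#'
#' @param x an `hvg_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.hvg_fit <- function(x, ...) {
  g <- x$genes[x$genes$evaluable, ]
  graphics::plot(g$log2_mean, g$log2_sd,
                 col = ifelse(g$hvg, "firebrick", "grey60"),
                 pch = 16, cex = 0.5,
                 xlab = "log2 mean normalized expression",
                 ylab = "log2 s.d.", ...)
  graphics::abline(x$coef[1], x$coef[2], col = "blue")
  graphics::abline(x$coef[1] + x$residual_cutoff, x$coef[2], col = "blue",
                   lty = 2)
  invisible(x)
}
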