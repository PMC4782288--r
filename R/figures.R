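## Report figures: per-metric dot plots with group-median lines, pooled
## caliber/distance histograms, and longitudinal perfusion medians with
## interquartile error bars.

#' Render the standard study figures
#'
#' Produces, for each compared metric, a dot plot with horizontal
#' group-median lines; pooled normalized caliber and distance histograms;
#' and longitudinal plots of the group medians of the tumor-wise median
#' enhancement metrics with interquartile-range error bars.  Figures with
#' missing metrics are skipped with a message.
#'
#' @param report a `StudyReport`.
#' @param dir output directory (created if needed).
#' @param format `"png"` or `"pdf"`.
#' @return invisibly, the vector of files written.
#' @export
makeStudyFigures <- function(report, dir, format = c("png", "pdf")) {
  stopifnot(inherits(report, "StudyReport"))
  format <- match.arg(format)
  if (nrow(report$perTumor) == 0) {
    message("empty report: no figures written")
    return(invisible(character(0)))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  dev <- function(path) if (format == "png")
    grDevices::png(path, width = 900, height = 700, res = 150)
  else grDevices::pdf(path, width = 6, height = 4.5)

  dotMetrics <- intersect(
    c("fbv", "vcP90", "fracVcGt150", "dnvMedian", "dnvP90", "fracDnvGt200",
      "pecDensity", "immatureFraction",
      grep("^deltaAuc_|^deltaFev_", names(report$perTumor), value = TRUE)),
    names(report$perTumor))
  for (m in dotMetrics) {
    df <- report$perTumor[, c("group", m)]
    names(df) <- c("group", "value")
    df <- df[!is.na(df$value), ]
    if (nrow(df) == 0) { message("metric ", m, " missing: figure skipped"); next }
    med <- stats::aggregate(value ~ group, df, median)
    gp <- ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$value)) +
      ggplot2::geom_jitter(width = 0.08, height = 0, size = 2, shape = 21,
                           fill = "grey40") +
      ggplot2::geom_errorbar(data = med,
                             ggplot2::aes(ymin = .data$value, ymax = .data$value),
                             width = 0.35, linewidth = 0.9) +
      ggplot2::labs(title = m, x = NULL, y = m) +
      ggplot2::theme_classic()
    path <- file.path(dir, paste0("dot_", m, ".", format))
    dev(path); print(gp); grDevices::dev.off()
    files <- c(files, path)
  }

  for (key in c("vc", "dnv")) {
    h <- report$histograms[[key]]
    if (is.null(h)) { message(key, " histogram missing: figure skipped"); next }
    gp <- ggplot2::ggplot(h, ggplot2::aes(x = .data$mid, y = .data$density,
                                          fill = .data$group)) +
      ggplot2::geom_col(position = "dodge", width = diff(sort(unique(h$mid)))[1] * 0.8) +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(0, .data$density - .data$mad),
                                          ymax = .data$density + .data$mad),
                             position = ggplot2::position_dodge(), width = 0) +
      ggplot2::labs(x = paste(toupper(key), "(um)"), y = "normalized frequency") +
      ggplot2::theme_classic()
    path <- file.path(dir, paste0("hist_", key, ".", format))
    dev(path); print(gp); grDevices::dev.off()
    files <- c(files, path)
  }

  aucCols <- grep("^medianAuc_day", names(report$perTumor), value = TRUE)
  if (length(aucCols) >= 2) {
    long <- do.call(rbind, lapply(aucCols, function(cn) {
      data.frame(group = report$perTumor$group,
                 day = as.numeric(sub("medianAuc_day", "", cn)),
                 value = report$perTumor[[cn]])
    }))
    long <- long[!is.na(long$value), ]
    agg <- do.call(rbind, lapply(split(long, list(long$group, long$day)), function(d) {
      data.frame(group = d$group[1], day = d$day[1],
                 med = median(d$value),
                 lo = interpPercentile(d$value, 0.25),
                 hi = interpPercentile(d$value, 0.75))
    }))
    gp <- ggplot2::ggplot(agg, ggplot2::aes(x = .data$day, y = .data$med,
                                            group = .data$group,
                                            shape = .data$group)) +
      ggplot2::geom_line() + ggplot2::geom_point(size = 2.5) +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                             width = 0.2) +
      ggplot2::labs(x = "day", y = "median AUC (first minute)") +
      ggplot2::theme_classic()
    path <- file.path(dir, paste0("longitudinal_auc.", format))
    dev(path); print(gp); grDevices::dev.off()
    files <- c(files, path)
  }
  invisible(files)
}
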