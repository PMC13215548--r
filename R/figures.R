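# Figure generation from pipeline artifacts: raw vs smoothed curves, mean
# curve with band, F statistic with critical lines, spatial and temporal
# effect summaries, and history-plus-forecast panels against the SDG line.

gg <- function(...) ggplot2::ggplot(...)

save_fig <- function(plot, path) {
  ggplot2::ggsave(path, plot, width = 8, height = 5, dpi = 120)
  path
}

have <- function(dir, f) file.exists(file.path(dir, f))

#' Render the standard figure set from pipeline artifacts
#'
#' Reads the CSV artifacts in `dir` and writes PNG figures under
#' `dir/figures`: raw and smoothed U5MR trajectories, the mean curve with
#' its 95% band, the F statistic with pointwise and global (max) critical
#' lines, posterior medians of the spatial (bar chart) and structured
#' temporal effects, and the per-region history plus forecast against a
#' horizontal SDG reference line. A missing artifact skips its figure with
#' a message.
#'
#' @param dir pipeline output directory.
#' @param sdg_threshold horizontal reference for the forecast figure, in
#'   deaths per 1000 live births (default 25, the SDG target).
#' @return character vector of figure paths written, invisibly.
#' @export
render_figures <- function(dir, sdg_threshold = 25) {
  if (!capabilities("png")) {
    message("render_figures: png device unavailable; skipping figures")
    return(invisible(character()))
  }
  figdir <- file.path(dir, "figures")
  dir.create(figdir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  aes <- ggplot2::aes

  if (have(dir, "estimates.csv")) {
    est <- read.csv(file.path(dir, "estimates.csv"))
    est <- est[!is.na(est$u5mr_per_1000), ]
    pl <- gg(est, aes(year, u5mr_per_1000, colour = region)) +
      ggplot2::geom_line(alpha = 0.8) + ggplot2::geom_point(size = 0.6) +
      ggplot2::labs(title = "Raw direct estimates of U5MR by region",
                    y = "U5MR per 1000 live births", x = NULL)
    written <- c(written, save_fig(pl, file.path(figdir, "raw_estimates.png")))
  } else message("render_figures: estimates.csv missing; skipping raw-estimates figure")

  if (have(dir, "posterior_summaries_rw2.csv")) {
    ps <- read.csv(file.path(dir, "posterior_summaries_rw2.csv"))
    sm <- ps[ps$effect == "u5mr", ]
    pl <- gg(sm, aes(year, median, colour = region)) +
      ggplot2::geom_line() +
      ggplot2::labs(title = "Smoothed U5MR by region (posterior median)",
                    y = "U5MR per 1000 live births", x = NULL)
    written <- c(written, save_fig(pl, file.path(figdir, "smoothed_estimates.png")))
    ph <- ps[ps$effect == "phi", ]
    pl <- gg(ph, aes(stats::reorder(region, median), median)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::geom_errorbar(aes(ymin = lower, ymax = upper), width = 0.25) +
      ggplot2::coord_flip() +
      ggplot2::labs(title = "Posterior median of ICAR spatial effects",
                    x = NULL, y = "logit-scale effect")
    written <- c(written, save_fig(pl, file.path(figdir, "spatial_effects.png")))
    ga <- ps[ps$effect == "gamma", ]
    pl <- gg(ga, aes(year, median)) +
      ggplot2::geom_ribbon(aes(ymin = lower, ymax = upper), fill = "grey80") +
      ggplot2::geom_line(colour = "firebrick") +
      ggplot2::labs(title = "Posterior median of the structured temporal effect",
                    y = "logit-scale effect", x = NULL)
    written <- c(written, save_fig(pl, file.path(figdir, "temporal_effect.png")))
  } else message("render_figures: posterior_summaries_rw2.csv missing; skipping model figures")

  if (have(dir, "mean_curve.csv")) {
    mc <- read.csv(file.path(dir, "mean_curve.csv"))
    pl <- gg(mc, aes(grid, mean)) +
      ggplot2::geom_ribbon(aes(ymin = lower, ymax = upper),
                           fill = "lightsteelblue") +
      ggplot2::geom_line(linewidth = 1) +
      ggplot2::labs(title = "Mean smoothed U5MR curve with 95% CI",
                    y = "U5MR per 1000 live births", x = NULL)
    written <- c(written, save_fig(pl, file.path(figdir, "mean_curve.png")))
  } else message("render_figures: mean_curve.csv missing; skipping mean-curve figure")

  if (have(dir, "fanova_results.csv")) {
    fa <- read.csv(file.path(dir, "fanova_results.csv"))
    pl <- gg(fa, aes(year, F_observed)) +
      ggplot2::geom_line(aes(colour = "observed F"), linewidth = 0.9) +
      ggplot2::geom_line(aes(y = pointwise_crit, colour = "pointwise critical"),
                         linetype = 2) +
      ggplot2::geom_hline(aes(yintercept = max_crit[1],
                              colour = "max (global) critical"),
                          linetype = 3) +
      ggplot2::scale_colour_manual(NULL, values = c(
        "observed F" = "firebrick", "pointwise critical" = "grey40",
        "max (global) critical" = "navy")) +
      ggplot2::labs(title = "Permutation F test across regions",
                    y = "F statistic", x = NULL)
    written <- c(written, save_fig(pl, file.path(figdir, "fanova_test.png")))
  } else message("render_figures: fanova_results.csv missing; skipping F-test figure")

  if (have(dir, "forecast.csv") && have(dir, "posterior_summaries_rw2.csv")) {
    fc <- read.csv(file.path(dir, "forecast.csv"))
    ps <- read.csv(file.path(dir, "posterior_summaries_rw2.csv"))
    hist <- ps[ps$effect == "u5mr", c("region", "year", "median")]
    if (nrow(fc)) {
      both <- rbind(cbind(hist, part = "history"),
                    cbind(fc[, c("region", "year", "median")], part = "forecast"))
      pl <- gg(both, aes(year, median, colour = region, linetype = part)) +
        ggplot2::geom_line() +
        ggplot2::geom_hline(yintercept = sdg_threshold, colour = "black",
                            linetype = 4) +
        ggplot2::annotate("text", x = min(both$year), y = sdg_threshold,
                          vjust = -0.5, hjust = 0, size = 3,
                          label = sprintf("SDG target: %g per 1000", sdg_threshold)) +
        ggplot2::labs(title = "Region-wise U5MR history and forecast",
                      y = "U5MR per 1000 live births", x = NULL)
      written <- c(written, save_fig(pl, file.path(figdir, "forecast.png")))
    }
  } else message("render_figures: forecast artifacts missing; skipping forecast figure")

  invisible(written)
}
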