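#' Render the report's standard figure set
#'
#' Writes up to eight PNG files: semi-automatic and automatic temperature
#' profiles, balance-board traces (total weight, leg shares, foot-region
#' shares), the CoP scatter with corner percentages, agreement-label bar
#' charts, regression scatters, Bland-Altman plots and the RMSE-vs-trend
#' comparison. Figures whose report section is empty are skipped with a
#' message. Profile-level figures use the example participant kept by
#' `run_config(keep_example = TRUE)`.
#'
#' @param report An `agreement_report` from [run_pipeline()].
#' @param dir Output directory (created).
#' @param width,height,dpi Device settings passed to [ggplot2::ggsave()].
#' @return Character vector of the files written.
#' @export
make_figures <- function(report, dir, width = 7, height = 5, dpi = 150) {
  stopifnot(inherits(report, "agreement_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  save_fig <- function(name, plot) {
    path <- file.path(dir, paste0(name, ".png"))
    ggplot2::ggsave(path, plot, width = width, height = height, dpi = dpi)
    written <<- c(written, path)
  }
  skip <- function(name) message("figure '", name, "' skipped: empty section")
  ex <- report$example

  prof_df <- function(profiles) do.call(rbind, lapply(profiles, function(p)
    data.frame(t_s = p$t_s, temp_c = p$temp_c, zone = attr(p, "zone"))))

  if (!is.null(ex$semi_profiles) && length(ex$semi_profiles)) {
    d <- prof_df(ex$semi_profiles)
    save_fig("semi_profiles",
      ggplot2::ggplot(d, ggplot2::aes(t_s, temp_c, colour = zone)) +
        ggplot2::geom_point() + ggplot2::geom_line() +
        ggplot2::labs(x = "time (s)", y = "temperature (degC)",
                      title = "Semi-automatic ROI extrema"))
  } else skip("semi_profiles")

  if (!is.null(ex$auto_profiles) && length(ex$auto_profiles)) {
    d <- prof_df(ex$auto_profiles)
    save_fig("auto_profiles",
      ggplot2::ggplot(d, ggplot2::aes(t_s, temp_c)) +
        ggplot2::geom_line(linewidth = 0.3) +
        ggplot2::facet_wrap(~zone, scales = "free_y") +
        ggplot2::labs(x = "time (s)", y = "temperature (degC)",
                      title = "Automatic keypoint profiles"))
  } else skip("auto_profiles")

  if (!is.null(ex$wbb)) {
    w <- ex$wbb
    d <- rbind(
      data.frame(t = w$t, value = w$total, series = "total (kg)"),
      data.frame(t = w$leg_shares$t, value = w$leg_shares$left,
                 series = "left-leg share"),
      data.frame(t = w$foot_shares$t, value = w$foot_shares$rear_left,
                 series = "left rearfoot share"))
    save_fig("wbb_traces",
      ggplot2::ggplot(d, ggplot2::aes(t, value)) +
        ggplot2::geom_line(linewidth = 0.3) +
        ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
        ggplot2::labs(x = "time (s)", y = NULL,
                      title = "Balance-board traces"))
    cpd <- w$cop[w$cop$valid, ]
    pct <- w$corner_pct
    ann <- data.frame(
      x = c(-1, 1, -1, 1) * 0.45 * max(abs(cpd$x_mm), 1),
      y = c(1, 1, -1, -1) * 0.45 * max(abs(cpd$y_mm), 1),
      lab = sprintf("%s %.1f%%", c("TL", "TR", "BL", "BR"),
                    100 * pct[c("tl", "tr", "bl", "br")]))
    save_fig("cop_scatter",
      ggplot2::ggplot(cpd, ggplot2::aes(x_mm, y_mm)) +
        ggplot2::geom_point(alpha = 0.2, size = 0.5) +
        ggplot2::geom_text(data = ann, ggplot2::aes(x, y, label = lab)) +
        ggplot2::labs(x = "medio-lateral (mm)", y = "antero-posterior (mm)",
                      title = "Centre of pressure"))
  } else { skip("wbb_traces"); skip("cop_scatter") }

  lc <- report$cohort$label_counts
  if (!is.null(lc)) {
    d <- rbind(cbind(lc$heating, mode = "heating"),
               cbind(lc$cooling, mode = "cooling"))
    save_fig("agreement_bars",
      ggplot2::ggplot(d, ggplot2::aes(label, count, fill = gender)) +
        ggplot2::geom_col(position = "dodge") +
        ggplot2::facet_wrap(~mode) +
        ggplot2::labs(title = "Inter-method agreement labels"))
  } else skip("agreement_bars")

  if (!is.null(ex$ba_points) && length(ex$ba_points)) {
    d <- do.call(rbind, lapply(names(ex$ba_points), function(rg)
      cbind(ex$ba_points[[rg]], region = rg)))
    save_fig("bland_altman",
      ggplot2::ggplot(d, ggplot2::aes(mean, diff)) +
        ggplot2::geom_point(colour = "darkgreen", shape = 18) +
        ggplot2::geom_hline(ggplot2::aes(yintercept = 0), linetype = 3) +
        ggplot2::facet_wrap(~region, scales = "free") +
        ggplot2::labs(x = "mean of methods (degC)",
                      y = "difference (degC)",
                      title = "Bland-Altman agreement"))
  } else skip("bland_altman")

  if (nrow(report$measurements)) {
    save_fig("regression_scatter",
      ggplot2::ggplot(report$measurements,
                      ggplot2::aes(region, r2, colour = strong)) +
        ggplot2::geom_jitter(width = 0.1, height = 0) +
        ggplot2::labs(y = expression(R^2),
                      title = "Inter-method determination per region"))
  } else skip("regression_scatter")

  rmse_rows <- do.call(rbind, lapply(report$participants, function(p)
    do.call(rbind, lapply(names(p$rmse), function(rg)
      data.frame(region = rg, auto = p$rmse[[rg]]$auto,
                 semi = p$rmse[[rg]]$semi)))))
  if (!is.null(rmse_rows) && nrow(rmse_rows)) {
    d <- rbind(data.frame(region = rmse_rows$region, method = "automatic",
                          rmse = rmse_rows$auto),
               data.frame(region = rmse_rows$region, method = "semi-automatic",
                          rmse = rmse_rows$semi))
    save_fig("rmse_trend",
      ggplot2::ggplot(d, ggplot2::aes(region, rmse, fill = method)) +
        ggplot2::geom_boxplot() +
        ggplot2::labs(y = "RMSE about linear trend (degC)",
                      title = "Trend residuals by method"))
  } else skip("rmse_trend")

  written
}
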