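#' Write the simulation report
#'
#' Emits the headline summary table (CSV), the per-iteration
#' cost-effectiveness plane points (CSV and scatter plot with
#' willingness-to-pay rays at 20,000 and 30,000 GBP/QALY and a 95%
#' ellipse), the cost-effectiveness acceptability curve (CSV and plot;
#' omitted when the threshold grid is empty), the mRS change bar data,
#' and a JSON run log (seed, iteration count, configuration, versions).
#'
#' @param results an `evtdes_results` object from [run_simulation()].
#' @param out_dir output directory; created if absent.
#' @param plots write PNG figures (default `TRUE`).
#' @return invisibly, the paths written.
#' @export
write_report <- function(results, out_dir, plots = TRUE) {
  stopifnot(inherits(results, "evtdes_results"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  paths <- character()
  s <- results$summary

  nbrow <- function(nb) data.frame(
    statistic = sprintf("net_benefit_%d", nb$wtp),
    estimate = nb$mean, ci_low = nb$ci[1], ci_high = nb$ci[2]
  )
  summary_df <- rbind(
    data.frame(statistic = "mean_time_to_treatment_reduction_min",
               estimate = s$time_delta$mean, ci_low = NA, ci_high = NA),
    data.frame(statistic = "sd_time_to_treatment_reduction_min",
               estimate = s$time_delta$sd, ci_low = NA, ci_high = NA),
    data.frame(statistic = paste0("mrs_change_", 0:6),
               estimate = unname(s$mrs_change), ci_low = NA, ci_high = NA),
    data.frame(statistic = "marginal_qalys", estimate = s$delta_qaly$mean,
               ci_low = s$delta_qaly$ci[1], ci_high = s$delta_qaly$ci[2]),
    data.frame(statistic = "marginal_cost_gbp", estimate = s$delta_cost$mean,
               ci_low = s$delta_cost$ci[1], ci_high = s$delta_cost$ci[2]),
    do.call(rbind, lapply(s$net_benefit, nbrow)),
    data.frame(statistic = "budget_impact_year1_gbp",
               estimate = s$budget_year1$mean,
               ci_low = s$budget_year1$ci[1], ci_high = s$budget_year1$ci[2]),
    data.frame(statistic = "budget_impact_years2to5_gbp",
               estimate = s$budget_years2to5$mean,
               ci_low = s$budget_years2to5$ci[1],
               ci_high = s$budget_years2to5$ci[2])
  )
  p <- file.path(out_dir, "summary.csv")
  write.csv(summary_df, p, row.names = FALSE)
  paths <- c(paths, p)

  plane <- results$per_iteration[, .(iteration, delta_qaly, delta_cost)]
  p <- file.path(out_dir, "ce_plane.csv")
  write.csv(plane, p, row.names = FALSE)
  paths <- c(paths, p)

  mrs_df <- data.frame(mrs = 0:6, delta = unname(results$mrs_change))
  p <- file.path(out_dir, "mrs_change.csv")
  write.csv(mrs_df, p, row.names = FALSE)
  paths <- c(paths, p)

  has_ceac <- length(results$config$economics$wtp_grid) > 0
  if (has_ceac) {
    p <- file.path(out_dir, "ceac.csv")
    write.csv(results$ceac, p, row.names = FALSE)
    paths <- c(paths, p)
  }

  if (plots) {
    g <- ggplot2::ggplot(plane,
                         ggplot2::aes(x = delta_qaly, y = delta_cost)) +
      ggplot2::geom_point(alpha = 0.4, size = 0.8) +
      ggplot2::stat_ellipse(level = 0.95, colour = "steelblue") +
      ggplot2::geom_abline(intercept = 0, slope = 20000,
                           linetype = "dashed") +
      ggplot2::geom_abline(intercept = 0, slope = 30000,
                           linetype = "dotted") +
      ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
      ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
      ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (GBP)",
                    title = "Cost-effectiveness plane",
                    subtitle = "Rays: £20,000 (dashed) and £30,000 (dotted) per QALY") +
      ggplot2::theme_minimal()
    p <- file.path(out_dir, "ce_plane.png")
    ggplot2::ggsave(p, g, width = 6, height = 5, dpi = 150)
    paths <- c(paths, p)

    if (has_ceac) {
      g <- ggplot2::ggplot(results$ceac,
                           ggplot2::aes(x = wtp, y = probability)) +
        ggplot2::geom_line() +
        ggplot2::scale_y_continuous(limits = c(0, 1)) +
        ggplot2::labs(x = "Willingness to pay (GBP per QALY)",
                      y = "Probability cost-effective",
                      title = "Cost-effectiveness acceptability curve") +
        ggplot2::theme_minimal()
      p <- file.path(out_dir, "ceac.png")
      ggplot2::ggsave(p, g, width = 6, height = 4, dpi = 150)
      paths <- c(paths, p)
    }

    g <- ggplot2::ggplot(mrs_df, ggplot2::aes(x = factor(mrs), y = delta)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::labs(x = "90-day mRS", y = "Mean change in patients/year",
                    title = "Population mRS change under reconfiguration") +
      ggplot2::theme_minimal()
    p <- file.path(out_dir, "mrs_change.png")
    ggplot2::ggsave(p, g, width = 6, height = 4, dpi = 150)
    paths <- c(paths, p)
  }

  log <- list(
    seed = results$seed,
    n_iterations = results$n_iterations,
    package_version = as.character(packageVersion("evtdes")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = serialise_config(results$config)
  )
  p <- file.path(out_dir, "run_log.json")
  jsonlite::write_json(log, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, p)

  invisible(paths)
}

# flatten a config into plain lists for the JSON run log
serialise_config <- function(cfg) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  strip(cfg)
}
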