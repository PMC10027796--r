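# Figures for the analysis pipeline: condition-mean bar charts, controller
# trajectories, and gaze-on-plane traces.

#' Bar chart of condition means with standard errors
#'
#' One panel per dependent variable, bars per target-side x cue condition —
#' the standard summary figure for the reaching measures.
#'
#' @param aggregates Data frame from \code{\link{aggregate_by_condition}}.
#' @param dvs Dependent variables to show.
#' @return A ggplot object.
#' @export
plot_condition_means <- function(aggregates,
                                 dvs = c("latency", "duration",
                                         "endpoint_error_target")) {
  long <- do.call(rbind, lapply(dvs, function(m) {
    data.frame(condition = paste(aggregates$target_side, aggregates$cue),
               measure = m,
               mean = aggregates[[paste0(m, "_mean")]],
               se = aggregates[[paste0(m, "_se")]],
               stringsAsFactors = FALSE)
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = condition, y = mean)) +
    ggplot2::geom_col(fill = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mean - se,
                                        ymax = mean + se),
                           width = 0.25, na.rm = TRUE) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Controller position traces aligned to the go cue
#'
#' Per-trial controller coordinates over time, relative to the go cue, one
#' panel per axis and one facet row per condition.
#'
#' @param session A completed session.
#' @param axis Which position axis to plot (\code{"x"}, \code{"y"} or
#'   \code{"z"}).
#' @return A ggplot object.
#' @export
plot_trajectories <- function(session, axis = "z") {
  col <- paste0("controller_pos_", axis)
  parts <- lapply(session$trials, function(t) {
    if (t$status != "done" || is.null(t$samples)) return(NULL)
    go <- event_time(t, "go_cue")
    data.frame(trial = t$number,
               condition = paste(t$params$target_side, t$params$cue),
               time = t$samples$time - go,
               pos = t$samples[[col]], stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, Filter(Negate(is.null), parts))
  ggplot2::ggplot(df, ggplot2::aes(x = time, y = pos,
                                   group = trial)) +
    ggplot2::geom_line(alpha = 0.4, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "time from go cue (s)",
                  y = paste0("controller ", axis, " (m)")) +
    ggplot2::theme_minimal()
}

#' Gaze position on the recording plane, aligned to the go cue
#'
#' Horizontal and vertical gaze-on-plane coordinates per trial.
#'
#' @param session A completed session.
#' @return A ggplot object.
#' @export
plot_gaze_on_plane <- function(session) {
  parts <- lapply(session$trials, function(t) {
    if (t$status != "done") return(NULL)
    g <- gaze_on_plane(t)
    if (nrow(g) == 0) return(NULL)
    rbind(data.frame(trial = t$number, axis = "horizontal (x)",
                     time = g$time, pos = g$x, stringsAsFactors = FALSE),
          data.frame(trial = t$number, axis = "vertical (y)",
                     time = g$time, pos = g$y, stringsAsFactors = FALSE))
  })
  df <- do.call(rbind, Filter(Negate(is.null), parts))
  ggplot2::ggplot(df, ggplot2::aes(x = time, y = pos,
                                   group = trial)) +
    ggplot2::geom_line(alpha = 0.3, linewidth = 0.3, na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::facet_wrap(~axis, ncol = 1) +
    ggplot2::labs(x = "time from go cue (s)",
                  y = "gaze on plane (m)") +
    ggplot2::theme_minimal()
}
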