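# ggplot2 displays ------------------------------------------------------------

#' @importFrom ggplot2 ggplot aes geom_point geom_abline geom_smooth labs
#'   geom_tile scale_fill_gradient2 theme_minimal geom_col autoplot
NULL

#' Predicted-vs-ultrasound gestational age scatter
#'
#' @param object A `clock_evaluation` (from [evaluate_predictions()] or the
#'   `cv` element of a `clock_fit`).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.clock_evaluation <- function(object, ...) {
  df <- attr(object, "predictions")
  ggplot(df, aes(x = .data$ga_ultrasound, y = .data$ga_metabolic)) +
    geom_point(alpha = 0.5, colour = "#2c7fb8") +
    geom_abline(slope = 1, intercept = 0, linetype = 2) +
    geom_smooth(method = "lm", formula = y ~ x, colour = "black",
                linewidth = 0.5) +
    labs(x = "Gestational age by ultrasound (weeks)",
         y = "Gestational age by metabolic clock (weeks)",
         title = sprintf("R = %.2f, RMSE = %.2f weeks", object$r,
                         object$rmse)) +
    theme_minimal()
}

#' Contribution bar chart for a sparse timing model
#'
#' @param object A `clock_model` or `logistic_clock_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.clock_model <- function(object, ...) {
  df <- tibble(term = names(object$contributions),
               contribution = as.numeric(object$contributions))
  ggplot(df, aes(x = stats::reorder(.data$term, .data$contribution),
                 y = .data$contribution)) +
    geom_col(fill = "#2c7fb8") +
    ggplot2::coord_flip() +
    labs(x = NULL, y = "Contribution |beta| / sum |beta|") +
    theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.logistic_clock_model <- function(object, ...) {
  autoplot.clock_model(object, ...)
}

#' Pathway-activity heatmap over gestational windows
#'
#' @param activity Output of [pathway_activity()].
#' @return A ggplot tile map (windows ordered by week, PP last).
#' @export
plot_pathway_activity <- function(activity) {
  lv <- unique(activity$window)
  num <- suppressWarnings(as.numeric(lv))
  lv <- lv[order(is.na(num), num)]
  activity$window <- factor(activity$window, levels = lv)
  ggplot(activity, aes(x = .data$window, y = .data$pathway_name,
                       fill = .data$activity)) +
    geom_tile() +
    scale_fill_gradient2(low = "#313695", mid = "white", high = "#a50026") +
    labs(x = "Adjusted gestational week", y = NULL,
         fill = "Activity\n(vs baseline)") +
    theme_minimal()
}

#' Deviation scatter against a subject-level outcome
#'
#' @param records Deviation records (see [per_subject_deviation()]).
#' @param against `"birthweight_residual"` or `"delivery_ga"`.
#' @return A ggplot.
#' @export
plot_deviation <- function(records, against = c("birthweight_residual",
                                                "delivery_ga")) {
  against <- match.arg(against)
  yvar <- if (against == "birthweight_residual") "birthweight_residual"
          else "delivery_ga_weeks"
  ylab <- if (against == "birthweight_residual")
    "Birth-weight residual (g, adjusted for delivery timing)"
  else "Delivery gestational age (weeks)"
  ggplot(records, aes(x = .data$mean_delta, y = .data[[yvar]])) +
    geom_point(colour = "#2c7fb8") +
    geom_smooth(method = "lm", formula = y ~ x, colour = "black",
                linewidth = 0.5) +
    labs(x = "Mean Δ(GA metabolic - GA ultrasound) (weeks)", y = ylab) +
    theme_minimal()
}
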