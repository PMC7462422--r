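#' Plot an I_diff profile
#'
#' Differential identifiability against the number of retained components,
#' with the optimum marked.
#'
#' @param object An `idiff_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.idiff_profile <- function(object, ...) {
  opt <- profile_optimum(object)
  df <- tidy(object)
  ggplot(df, aes(x = .data$m, y = .data$I_diff)) +
    geom_line(colour = "#b2182b") +
    geom_point(size = 0.8) +
    geom_vline(xintercept = opt$m_star, linetype = "dashed", colour = "grey40") +
    annotate("text", x = opt$m_star, y = max(df$I_diff), hjust = -0.1, vjust = 1,
             label = sprintf("m* = %d", opt$m_star), size = 3) +
    labs(x = "number of principal components (m)",
         y = expression(I[diff]),
         title = attr(object, "property") %||% NULL,
         subtitle = attr(object, "condition") %||% NULL) +
    theme_minimal()
}

#' Plot all I_diff profiles of a study
#'
#' One panel per condition, profiles coloured by property and faceted by
#' scenario, mirroring the familiar I_diff-versus-components figures.
#'
#' @param object An `idiff_study`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.idiff_study <- function(object, ...) {
  ggplot(object$profiles,
         aes(x = .data$m, y = .data$I_diff, colour = .data$property)) +
    geom_line() +
    facet_grid(rows = vars(.data$scenario), cols = vars(.data$condition)) +
    labs(x = "number of principal components (m)", y = expression(I[diff]),
         colour = "property") +
    theme_minimal()
}

#' Heatmap of an identifiability matrix
#'
#' @param object An `identifiability_result`.
#' @param ... Unused.
#' @return A ggplot; a visible diagonal indicates a subject fingerprint.
#' @export
autoplot.identifiability_result <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$retest_subject, y = .data$test_subject,
                 fill = .data$correlation)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                         limits = c(-1, 1)) +
    scale_y_discrete(limits = rev) +
    labs(x = "retest", y = "test",
         title = sprintf("I_diff = %.2f", object$I_diff)) +
    theme_minimal() +
    theme(axis.text = element_blank())
}

#' Distribution of per-feature task-sensitivity ICCs
#'
#' @param object An `icc_table` from [task_sensitivity()].
#' @param ... Unused.
#' @return A ggplot of ICC distributions per property and variant.
#' @export
autoplot.icc_table <- function(object, ...) {
  ggplot(object, aes(x = .data$variant, y = .data$mean_icc, fill = .data$variant)) +
    geom_boxplot(outlier.size = 0.3, show.legend = FALSE) +
    facet_wrap(vars(.data$property)) +
    labs(x = NULL, y = "mean ICC across subjects") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 30, hjust = 1))
}
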