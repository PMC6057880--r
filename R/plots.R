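GROUP_COLORS <- c(progression = "#3B6FB6", suppression = "#E8B820",
                  regression = "#C23B22")

#' Waterfall plot of T/C response scores
#'
#' Per-model T/C percentages sorted in descending order, colored by
#' response group (progression blue, suppression yellow, regression
#' red). Optionally colored instead by an expression bin (e.g. ABCB1),
#' the resistance-biomarker view of the same trial.
#'
#' @param calls classified response calls ([response_calls()]).
#' @param fill_by optional named vector (model_id -> level of a factor,
#'   e.g. [bin_expression()] output) to color bars by instead of the
#'   response group.
#' @return a ggplot object.
#' @export
plot_waterfall <- function(calls, fill_by = NULL) {
  wf <- waterfall(calls)
  wf$model_id <- factor(wf$model_id, levels = wf$model_id)
  if (is.null(fill_by)) {
    wf$fill <- factor(wf$group, levels = names(GROUP_COLORS))
    scale <- ggplot2::scale_fill_manual(values = GROUP_COLORS,
                                        name = "response")
  } else {
    wf$fill <- fill_by[as.character(wf$model_id)]
    scale <- ggplot2::scale_fill_manual(
      values = c(low = "#3B6FB6", mid = "#E8B820", high = "#C23B22"),
      name = "expression"
    )
  }
  ggplot2::ggplot(wf, ggplot2::aes(x = .data$model_id, y = .data$tc_percent,
                                   fill = .data$fill)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(0, 50), linetype = "dashed",
                        linewidth = 0.3) +
    scale +
    ggplot2::labs(x = NULL, y = "T/C (%)") +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}

#' Kaplan-Meier step plot by response group
#'
#' @param records survival records ([doubling_events()]).
#' @return a ggplot object.
#' @export
plot_km <- function(records) {
  groups <- intersect(names(GROUP_COLORS), unique(records$group))
  steps <- do.call(rbind, lapply(groups, function(g) {
    r <- records[records$group == g, , drop = FALSE]
    km <- km_fit(r$time_days, r$event)
    data.frame(group = g,
               time = c(0, km$time),
               surv = c(1, km$surv),
               stringsAsFactors = FALSE)
  }))
  steps$group <- factor(steps$group, levels = names(GROUP_COLORS))
  ggplot2::ggplot(steps, ggplot2::aes(x = .data$time, y = .data$surv,
                                      color = .data$group)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::scale_color_manual(values = GROUP_COLORS, name = "response") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "days of treatment",
                  y = "progression-free survival\n(tumor not yet doubled)") +
    ggplot2::theme_classic()
}

#' Volcano plot of differential-expression results
#'
#' @param de_results output of [de_test()].
#' @param q_cutoff significance threshold on the BH q-value.
#' @param label_genes genes to annotate by name.
#' @return a ggplot object.
#' @export
plot_volcano <- function(de_results, q_cutoff = 0.05,
                         label_genes = character(0)) {
  v <- volcano(de_results, q_cutoff)
  p <- ggplot2::ggplot(v, ggplot2::aes(x = .data$log2fc,
                                       y = .data$neg_log10_p,
                                       color = .data$significant)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60",
                                           `TRUE` = "#C23B22"),
                                name = sprintf("q <= %.2g", q_cutoff)) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p") +
    ggplot2::theme_classic()
  lab <- v[v$gene %in% label_genes, , drop = FALSE]
  if (nrow(lab)) {
    p <- p + ggplot2::geom_text(data = lab,
                                ggplot2::aes(label = .data$gene),
                                vjust = -0.8, size = 3, color = "black",
                                show.legend = FALSE)
  }
  p
}

#' Oncoprint tile plot
#'
#' Gene x sample mutation grid with samples grouped by response;
#' low-confidence calls are drawn transparent.
#'
#' @param op an [oncoprint()] result.
#' @return a ggplot object.
#' @export
plot_oncoprint <- function(op) {
  stopifnot(inherits(op, "pdx_oncoprint"))
  mat <- op$matrix
  df <- expand.grid(gene = rownames(mat), sample = colnames(mat),
                    stringsAsFactors = FALSE)
  df$state <- mat[cbind(df$gene, df$sample)]
  df$group <- op$groups[df$sample]
  df$sample <- factor(df$sample, levels = colnames(mat))
  df$gene <- factor(df$gene, levels = rev(rownames(mat)))
  df$mutated <- df$state != "none"
  df$alpha <- ifelse(df$state == "mutated_low_conf", 0.4, 1)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$gene)) +
    ggplot2::geom_tile(fill = "grey92", color = "white") +
    ggplot2::geom_tile(
      data = df[df$mutated, , drop = FALSE],
      ggplot2::aes(fill = .data$group, alpha = .data$alpha),
      color = "white"
    ) +
    ggplot2::scale_fill_manual(values = GROUP_COLORS, name = "response") +
    ggplot2::scale_alpha_identity() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}
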