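# ggplot2 views of benchmark results and diagnostics.

condition_label <- function(results) {
  paste0(results$strategy,
         ifelse(results$anchor_ratio > 0,
                paste0(ifelse(results$paired, " paired@", " unpaired@"),
                       results$anchor_ratio),
                ""))
}

#' Plot per-repeat benchmark metrics by condition
#'
#' Boxplots of a chosen metric across repeats, one box per experimental
#' condition (strategy, paired/unpaired, anchor ratio) and model.
#'
#' @param object A `ddg_benchmark` tibble.
#' @param metric Metric column to plot (default `"pearson"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ddg_benchmark
#' @export
autoplot.ddg_benchmark <- function(object, metric = "pearson", ...) {
  df <- as_tibble(object)
  df <- df[!df$failed, ]
  df$condition <- condition_label(df)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data[[metric]],
                                   fill = .data$model)) +
    ggplot2::geom_boxplot(alpha = 0.7, outlier.size = 0.8) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Anchor-ratio response curve
#'
#' Mean +/- SD of a metric as a function of the anchor ratio, one line per
#' strategy arm (paired vs. unpaired), the standard view of how prediction
#' quality responds to the amount of reference data.
#'
#' @param results A `ddg_benchmark` tibble covering several anchor ratios
#'   (e.g. from [compare_anchor_strategies()]).
#' @param metric Metric to plot (default `"pearson"`).
#' @return A ggplot object.
#' @export
plot_anchor_curve <- function(results, metric = "pearson") {
  s <- summarize_benchmark(results)
  s <- s[s$metric == metric, ]
  s$arm <- ifelse(s$anchor_ratio == 0, "baseline",
                  ifelse(s$paired, "paired", "unpaired"))
  # the ratio-0 baseline applies to both arms
  base <- s[s$arm == "baseline", ]
  if (nrow(base)) {
    s <- bind_rows(s[s$arm != "baseline", ],
                   mutate(base, arm = "paired"),
                   mutate(base, arm = "unpaired"))
  }
  ggplot2::ggplot(s, ggplot2::aes(x = .data$anchor_ratio, y = .data$mean,
                                  colour = .data$arm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.02) +
    ggplot2::labs(x = "anchor ratio", y = paste("mean", metric),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Train/test similarity distributions
#'
#' Histograms of per-test-record maximum sequence identity and maximum
#' ligand Tanimoto similarity to the training set.
#'
#' @param object A `ddg_leakage` tibble from [leakage_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ddg_leakage
#' @export
autoplot.ddg_leakage <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as_tibble(object)[, c("max_seq_identity", "max_smiles_tanimoto")],
    cols = dplyr::everything(),
    names_to = "measure", values_to = "percent"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$percent)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "max similarity to training set (%)", y = "test records") +
    ggplot2::theme_minimal()
}

#' Confusion matrix tile plot
#'
#' @param object A `ddg_classification` from [classify_resistance()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ddg_classification
#' @export
autoplot.ddg_classification <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), colour = "white") +
    ggplot2::scale_fill_gradient(low = "grey40", high = "firebrick") +
    ggplot2::labs(title = paste0("threshold ", format(object$threshold),
                                 " kcal/mol")) +
    ggplot2::theme_minimal()
}
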