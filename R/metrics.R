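#' Regression metrics for ddG prediction
#'
#' Computes the four standard agreement measures between experimental and
#' predicted ddG values: mean absolute error
#' \eqn{MAE = \frac{1}{n}\sum |y_i - \hat y_i|}, root mean square error
#' \eqn{RMSE = \sqrt{\frac{1}{n}\sum (y_i - \hat y_i)^2}}, the Pearson
#' product-moment correlation, and the Spearman rank correlation (Pearson
#' on average-ranked data, which reduces to
#' \eqn{1 - 6\sum d_i^2 / (n(n^2-1))} when there are no ties).
#'
#' When either side has zero variance the correlations are undefined; they
#' are returned as `NA` with `degenerate = TRUE` while MAE/RMSE are still
#' reported.
#'
#' @param data A data frame holding both columns.
#' @param truth,estimate Column names (tidy-eval) of the experimental and
#'   predicted values, in kcal/mol.
#' @return A one-row tibble: `n`, `mae`, `rmse`, `pearson`, `spearman`,
#'   `degenerate`.
#' @examples
#' compute_metrics(data.frame(y = c(1, 2), p = c(2, 4)), y, p)
#' @export
compute_metrics <- function(data, truth, estimate) {
  y <- rlang::eval_tidy(enquo(truth), data)
  yhat <- rlang::eval_tidy(enquo(estimate), data)
  as_tibble(c(list(n = length(y)), metrics_vec(y, yhat)))
}

metrics_vec <- function(y, yhat) {
  if (length(y) != length(yhat)) stop_ddg("truth and estimate lengths differ.")
  if (length(y) < 2L) stop_ddg("need at least 2 observations.")
  if (any(!is.finite(y)) || any(!is.finite(yhat))) {
    stop_ddg("metrics require finite values.")
  }
  degenerate <- sd(y) == 0 || sd(yhat) == 0
  list(
    mae = mean(abs(y - yhat)),
    rmse = sqrt(mean((y - yhat)^2)),
    pearson = if (degenerate) NA_real_ else cor(y, yhat),
    spearman = if (degenerate) NA_real_ else cor(y, yhat, method = "spearman"),
    degenerate = degenerate
  )
}

#' Resistance threshold from an affinity fold change
#'
#' Converts an x-fold change in binding affinity (e.g. IC50) into the
#' equivalent free energy difference \eqn{R T \ln(fold)} with
#' \eqn{R = 1.987 \times 10^{-3}} kcal/(mol K). The conventional
#' resistant/susceptible boundary of a 10-fold change at 298 K is
#' 1.36 kcal/mol.
#'
#' @param fold Fold change, must be > 1.
#' @param temperature_K Absolute temperature in Kelvin (default 298).
#' @return Threshold in kcal/mol.
#' @examples
#' threshold_from_fold_change(10)  # ~1.36
#' @export
threshold_from_fold_change <- function(fold = 10, temperature_K = 298) {
  assert_scalar_number(fold, "fold")
  assert_scalar_number(temperature_K, "temperature_K")
  if (fold <= 1) stop_ddg("`fold` must be greater than 1.")
  if (temperature_K <= 0) stop_ddg("`temperature_K` must be positive.")
  1.987e-3 * temperature_K * log(fold)
}

#' Resistant/susceptible classification report
#'
#' Labels each record resistant (R) when its ddG meets the threshold and
#' susceptible (S) otherwise, applies the same rule to truth and
#' predictions, and reports the 2x2 confusion matrix, accuracy, and the
#' rank-based (Mann-Whitney) AUC using the predicted ddG as a continuous
#' score against the true labels. When the truth contains a single class
#' the AUC is undefined and returned as `NA`.
#'
#' @param data A data frame holding both columns.
#' @param truth,estimate Column names (tidy-eval) of experimental and
#'   predicted ddG.
#' @param threshold Boundary in kcal/mol (default 1.36, a 10-fold IC50
#'   change at 298 K).
#' @param boundary `"geq"` (default): ddG >= threshold is resistant;
#'   `"gt"`: strict inequality.
#' @return An object of class `ddg_classification`; [tidy()] returns the
#'   confusion cells in long form, [glance()] the scalar summary.
#' @export
classify_resistance <- function(data, truth, estimate, threshold = 1.36,
                                boundary = c("geq", "gt")) {
  boundary <- match.arg(boundary)
  y <- rlang::eval_tidy(enquo(truth), data)
  yhat <- rlang::eval_tidy(enquo(estimate), data)
  if (length(y) != length(yhat)) stop_ddg("truth and estimate lengths differ.")
  lab <- function(v) {
    r <- if (boundary == "geq") v >= threshold else v > threshold
    factor(ifelse(r, "R", "S"), levels = c("R", "S"))
  }
  true_lab <- lab(y)
  pred_lab <- lab(yhat)
  confusion <- table(truth = true_lab, predicted = pred_lab)
  structure(
    list(threshold = threshold, boundary = boundary, confusion = confusion,
         accuracy = mean(true_lab == pred_lab),
         auc = rank_auc(scores = yhat, positive = true_lab == "R"),
         n = length(y)),
    class = "ddg_classification"
  )
}

# Mann-Whitney AUC: P(score_R > score_S) + 0.5 P(tie), via average ranks.
rank_auc <- function(scores, positive) {
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' @export
print.ddg_classification <- function(x, ...) {
  cat("<ddg_classification> threshold ", format(x$threshold),
      " kcal/mol (", x$boundary, "), n = ", x$n, "\n", sep = "")
  print(x$confusion)
  cat("accuracy: ", format(x$accuracy, digits = 3),
      "  AUC: ", format(x$auc, digits = 3), "\n", sep = "")
  invisible(x)
}

#' @method tidy ddg_classification
#' @export
tidy.ddg_classification <- function(x, ...) {
  df <- as.data.frame(x$confusion)
  tibble(truth = df$truth, predicted = df$predicted, count = df$Freq)
}

#' @method glance ddg_classification
#' @export
glance.ddg_classification <- function(x, ...) {
  tibble(threshold = x$threshold, n = x$n,
         n_resistant = sum(x$confusion["R", ]),
         n_susceptible = sum(x$confusion["S", ]),
         accuracy = x$accuracy, auc = x$auc)
}

#' Metrics stratified by mutation location
#'
#' Splits records into three bins by the minimum residue-ligand distance —
#' binding pocket (< 8 A), intermediate (8-15 A, inclusive) and distal
#' (> 15 A) — and computes the full metric set per bin. Records without a
#' distance are excluded and counted.
#'
#' @param data A data frame with the distance column and both ddG columns.
#' @param truth,estimate Column names (tidy-eval) of experimental and
#'   predicted ddG.
#' @param distance Column name (tidy-eval) of the distance in Angstrom.
#' @return A tibble with one row per bin (`location`, `n`, then the metric
#'   columns; `NA` metrics for bins with fewer than 2 records) and
#'   attribute `n_excluded` counting records lacking a distance.
#' @export
stratify_by_location <- function(data, truth, estimate, distance = distance) {
  y <- rlang::eval_tidy(enquo(truth), data)
  yhat <- rlang::eval_tidy(enquo(estimate), data)
  d <- rlang::eval_tidy(enquo(distance), data)
  keep <- !is.na(d)
  n_excluded <- sum(!keep)
  y <- y[keep]; yhat <- yhat[keep]; d <- d[keep]
  bins <- c("pocket", "intermediate", "distal")
  location <- factor(ifelse(d < 8, "pocket",
                            ifelse(d <= 15, "intermediate", "distal")),
                     levels = bins)
  out <- lapply(bins, function(b) {
    ii <- which(location == b)
    if (length(ii) < 2L) {
      tibble(location = b, n = length(ii), mae = NA_real_, rmse = NA_real_,
             pearson = NA_real_, spearman = NA_real_, degenerate = NA)
    } else {
      as_tibble(c(list(location = b, n = length(ii)),
                  metrics_vec(y[ii], yhat[ii])))
    }
  })
  out <- bind_rows(out)
  attr(out, "n_excluded") <- n_excluded
  out
}
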