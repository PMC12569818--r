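# Brute-force metric implementations straight from the defining formulas,
# kept independent of the package implementation.
brute_metrics <- function(y, yhat) {
  n <- length(y)
  mae <- sum(abs(y - yhat)) / n
  rmse <- sqrt(sum((y - yhat)^2) / n)
  pearson <- sum((y - mean(y)) * (yhat - mean(yhat))) /
    sqrt(sum((y - mean(y))^2) * sum((yhat - mean(yhat))^2))
  ry <- rank(y); rp <- rank(yhat)  # average ranks for ties
  spearman <- sum((ry - mean(ry)) * (rp - mean(rp))) /
    sqrt(sum((ry - mean(ry))^2) * sum((rp - mean(rp))^2))
  c(mae = mae, rmse = rmse, pearson = pearson, spearman = spearman)
}

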