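#' ROC curve of Ki-67 against luminal subtype
#'
#' Positives are luminal B (the higher-proliferation class). Thresholds are
#' the midpoints between adjacent distinct observed values plus -Inf/+Inf; a
#' case is called positive when its value exceeds the threshold. AUC is the
#' trapezoidal area, equal to the Mann-Whitney statistic U/(n1*n2) with the
#' half-tie convention.
#'
#' @param labels logical or two-level vector; TRUE / "B" = positive class.
#' @param values Ki-67 percent.
#' @return object of class `roc_result`: thresholds, sensitivity,
#'   specificity, auc, youden_cut.
#' @export
roc_curve <- function(labels, values) {
  pos <- if (is.logical(labels)) labels else labels %in% c("B", "b", 1, "1")
  stopifnot(length(pos) == length(values), !any(is.na(values)))
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop_ki67("both classes must be present", "ki67cta_config_error")
  v <- sort(unique(values))
  thr <- c(-Inf, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2, Inf)
  sens <- vapply(thr, function(t) mean(values[pos] > t), numeric(1))
  spec <- vapply(thr, function(t) mean(values[!pos] <= t), numeric(1))
  # Mann-Whitney AUC with half credit for ties
  r <- rank(values)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  res <- structure(list(thresholds = thr, sensitivity = sens,
                        specificity = spec, auc = auc,
                        n_pos = n1, n_neg = n0),
                   class = "roc_result")
  res$youden_cut <- youden_cutpoint(res)
  res
}

#' Youden-optimal cut-point
#'
#' Maximizes J = sensitivity + specificity - 1 over the ROC thresholds,
#' breaking ties toward the lower threshold. The infinite end thresholds
#' can never win ties against an interior one (J = 0 there).
#'
#' @param roc a `roc_result`.
#' @return the optimal threshold (percent Ki-67).
#' @export
youden_cutpoint <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  j <- roc$sensitivity + roc$specificity - 1
  finite <- is.finite(roc$thresholds)
  # tie-break toward the lower threshold; prefer finite thresholds
  best <- max(j)
  cand <- which(j >= best - 1e-12)
  cand_f <- cand[finite[cand]]
  if (length(cand_f) > 0) roc$thresholds[min(cand_f)]
  else roc$thresholds[min(cand)]
}

#' Youden J at a given threshold
#' @param roc a `roc_result`.
#' @param cut threshold.
#' @return sensitivity + specificity - 1 at the nearest ROC threshold.
#' @export
youden_at <- function(roc, cut) {
  i <- which.min(abs(roc$thresholds - cut))
  roc$sensitivity[i] + roc$specificity[i] - 1
}
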