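#' Two-rater 2x2 contingency table at a cut-point
#'
#' Cross-classifies the above / at-or-below calls of both raters. Rater A is
#' the reference (rows): a = both above, b = A above & B at/below, c = A
#' at/below & B above, d = both at/below. "Positive" means above the
#' cut-point (the unfavorable side). Pairs with a missing score are
#' excluded and their count recorded.
#'
#' @param pairs data frame with score_a, score_b (percent), e.g. from
#'   [generate_paired_scores()].
#' @param cutpoint percent.
#' @return object of class `contingency_2x2` with a, b, c, d, n, cutpoint,
#'   n_missing.
#' @export
contingency <- function(pairs, cutpoint) {
  stopifnot(is.data.frame(pairs), all(c("score_a", "score_b") %in%
                                        names(pairs)))
  if (nrow(pairs) == 0) stop_ki67("empty paired-score table",
                                  "ki67cta_config_error")
  ok <- !is.na(pairs$score_a) & !is.na(pairs$score_b)
  pa <- !at_or_below(pairs$score_a[ok], cutpoint)   # TRUE = above = positive
  pb <- !at_or_below(pairs$score_b[ok], cutpoint)
  contingency_2x2(a = sum(pa & pb), b = sum(pa & !pb),
                  c = sum(!pa & pb), d = sum(!pa & !pb),
                  cutpoint = cutpoint, n_missing = sum(!ok))
}

#' Build a contingency table from counts
#' @param a,b,c,d cell counts (reference rater A in rows; a = both above).
#' @param cutpoint optional percent label.
#' @param n_missing excluded pairs.
#' @return object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d, cutpoint = NA_real_,
                            n_missing = 0L) {
  if (any(c(a, b, c, d) < 0) || a + b + c + d < 1)
    stop_ki67("invalid contingency counts", "ki67cta_config_error")
  structure(list(a = a, b = b, c = c, d = d, n = a + b + c + d,
                 cutpoint = cutpoint, n_missing = n_missing),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat(sprintf("<2x2 at %s%%: a=%d b=%d c=%d d=%d (n=%d)>\n",
              format(x$cutpoint), x$a, x$b, x$c, x$d, x$n))
  invisible(x)
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' Beta-quantile form: lower = qbeta(alpha/2, x, n-x+1), upper =
#' qbeta(1-alpha/2, x+1, n-x); lower is 0 at x = 0 and upper is 1 at x = n.
#'
#' @param successes,trials integers, 0 <= successes <= trials, trials >= 1.
#' @param level confidence level (default 0.95).
#' @return named numeric `c(lower, upper)`.
#' @export
clopper_pearson <- function(successes, trials, level = 0.95) {
  if (trials < 1 || successes < 0 || successes > trials ||
      successes != round(successes) || trials != round(trials))
    stop_ki67("need integers 0 <= successes <= trials, trials >= 1",
              "ki67cta_config_error")
  alpha <- 1 - level
  lower <- if (successes == 0) 0 else
    stats::qbeta(alpha / 2, successes, trials - successes + 1)
  upper <- if (successes == trials) 1 else
    stats::qbeta(1 - alpha / 2, successes + 1, trials - successes)
  c(lower = lower, upper = upper)
}

#' Percent positive and negative agreement with exact intervals
#'
#' PPA = a/(a+b), NPA = d/(c+d), relative to reference rater A; each with
#' its Clopper-Pearson interval. An empty margin leaves that proportion NA.
#'
#' @param table a `contingency_2x2`.
#' @param level confidence level.
#' @return list `ppa` and `npa`, each with estimate, lower, upper, k, n.
#' @export
ppa_npa <- function(table, level = 0.95) {
  stopifnot(inherits(table, "contingency_2x2"))
  one <- function(k, n) {
    if (n < 1)
      return(list(estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                  k = k, n = n))
    ci <- clopper_pearson(k, n, level)
    list(estimate = k / n, lower = ci[["lower"]], upper = ci[["upper"]],
         k = k, n = n)
  }
  list(ppa = one(table$a, table$a + table$b),
       npa = one(table$d, table$c + table$d))
}

#' Cohen's kappa for a 2x2 table
#'
#' kappa = (p_o - p_e) / (1 - p_e) with p_o = (a+d)/n and p_e the product of
#' the marginals. The confidence interval uses the large-sample
#' Fleiss-Cohen-Everitt standard error and is truncated to \[-1, 1\].
#'
#' @param table a `contingency_2x2`.
#' @param level confidence level.
#' @return list: kappa, lower, upper, se, p_o, p_e, n; kappa is NA with a
#'   degenerate chance agreement (p_e = 1).
#' @export
cohen_kappa <- function(table, level = 0.95) {
  stopifnot(inherits(table, "contingency_2x2"))
  a <- table$a; b <- table$b; cc <- table$c; d <- table$d; n <- table$n
  if (n < 2) stop_ki67("need n >= 2", "ki67cta_config_error")
  p <- matrix(c(a, b, cc, d), 2, 2, byrow = TRUE) / n
  po <- p[1, 1] + p[2, 2]
  rowm <- rowSums(p); colm <- colSums(p)
  pe <- sum(rowm * colm)
  if (1 - pe < 1e-12)
    return(list(kappa = NA_real_, lower = NA_real_, upper = NA_real_,
                se = NA_real_, p_o = po, p_e = pe, n = n))
  kappa <- (po - pe) / (1 - pe)
  # Fleiss, Cohen & Everitt (1969) large-sample variance
  term1 <- sum(diag(p) * (1 - (rowm + colm) * (1 - kappa))^2)
  term2 <- (1 - kappa)^2 *
    (p[1, 2] * (colm[1] + rowm[2])^2 + p[2, 1] * (colm[2] + rowm[1])^2)
  term3 <- (kappa - pe * (1 - kappa))^2
  se <- sqrt(max(0, term1 + term2 - term3)) / ((1 - pe) * sqrt(n))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(kappa = kappa,
       lower = max(-1, kappa - z * se), upper = min(1, kappa + z * se),
       se = se, p_o = po, p_e = pe, n = n)
}

#' Pearson and Spearman correlation of paired scores
#'
#' @param pairs data frame with score_a, score_b; needs n >= 3 and nonzero
#'   variance in both raters (else NA with a warning).
#' @return list: pearson, spearman, n.
#' @export
correlations <- function(pairs) {
  ok <- !is.na(pairs$score_a) & !is.na(pairs$score_b)
  x <- pairs$score_a[ok]; y <- pairs$score_b[ok]
  if (length(x) < 3) stop_ki67("need n >= 3 complete pairs",
                               "ki67cta_config_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant scores: correlations undefined")
    return(list(pearson = NA_real_, spearman = NA_real_, n = length(x)))
  }
  list(pearson = stats::cor(x, y, method = "pearson"),
       spearman = stats::cor(x, y, method = "spearman"),
       n = length(x))
}

#' Bland-Altman bias and limits of agreement
#'
#' @param pairs data frame with score_a, score_b; n >= 2.
#' @return list: bias = mean(A-B), sd, lower/upper limits (bias +- 1.96 sd),
#'   and a data frame of (mean, difference) coordinates for plotting.
#' @export
bland_altman <- function(pairs) {
  ok <- !is.na(pairs$score_a) & !is.na(pairs$score_b)
  a <- pairs$score_a[ok]; b <- pairs$score_b[ok]
  if (length(a) < 2) stop_ki67("need n >= 2 complete pairs",
                               "ki67cta_config_error")
  d <- a - b
  bias <- mean(d); s <- stats::sd(d)
  list(bias = bias, sd = s,
       lower = bias - 1.96 * s, upper = bias + 1.96 * s,
       points = data.frame(mean = (a + b) / 2, difference = d))
}

#' One Table-1-style row of agreement statistics
#'
#' @param pairs paired scores.
#' @param cutpoint percent.
#' @param method label carried into the output.
#' @param sample_set label carried into the output.
#' @return list mirroring a summary-table row: sample_set, cutpoint, method,
#'   n, ppa/npa (percent with CI), kappa (with CI).
#' @export
agreement_row <- function(pairs, cutpoint, method = "SOP",
                          sample_set = "synthetic") {
  tab <- contingency(pairs, cutpoint)
  pn <- ppa_npa(tab)
  kp <- cohen_kappa(tab)
  pct <- function(p) {
    p[c("estimate", "lower", "upper")] <-
      lapply(p[c("estimate", "lower", "upper")], function(v) 100 * v)
    p
  }
  list(sample_set = sample_set, cutpoint = cutpoint, method = method,
       n = tab$n, table = unclass(tab)[c("a", "b", "c", "d")],
       ppa = pct(pn$ppa), npa = pct(pn$npa),
       kappa = kp[c("kappa", "lower", "upper")])
}
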