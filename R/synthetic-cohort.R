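#' Cohort simulation configuration
#'
#' The synthetic cohort emulates an ER+ neoadjuvant endocrine therapy trial
#' population: baseline Ki-67 is a two-component luminal A/B log-normal
#' mixture, on-treatment values are baseline times a label-specific
#' suppression factor (luminal A suppresses strongly, B weakly), and
#' relapse-free survival is exponential with one hazard per case resolved by
#' priority modified-PEPI-0 > month-1 Ki-67 above 10% > remainder. The
#' default modified-PEPI-0 hazard is exactly 0, so that stratum has zero
#' events by construction.
#'
#' @param n_cases number of patients.
#' @param luminal_weights mixture weights for (A, B); must sum to 1.
#' @param meanlog_a,meanlog_b,sdlog_a,sdlog_b log-normal parameters for the
#'   baseline Ki-67 *fraction* per subtype. Defaults: medians 5% and 25%
#'   with sdlog 0.45 (A) and 0.85 (B) - luminal B is the more heterogeneous
#'   class - calibrated so the class-conditional densities cross near 10%
#'   (the Youden-optimal cut) and the mixture AUC is about 0.95.
#' @param supp_month1_a,supp_month1_b median month-1 suppression factors
#'   per subtype (log-normal, sdlog `supp_sdlog`).
#' @param supp_surgical median surgical/month-1 suppression factor.
#' @param supp_sdlog sdlog of all suppression factors.
#' @param hazard_pepi0,hazard_gt10,hazard_le10 exponential relapse hazards
#'   per month for the modified-PEPI-0 stratum, the month-1 Ki-67 > 10%
#'   stratum, and everyone else (defaults 0, 0.008, 0.002: hazard ratio 4
#'   across the 10% cut).
#' @param censoring_rate probability of early drop-out censoring.
#' @param fu_min,fu_max administrative follow-up window in months.
#' @param pt_probs probabilities of pathological stage pT1..pT4.
#' @param p_n0 probability of node-negative (N0) status.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_cases = 200,
                          luminal_weights = c(A = 0.55, B = 0.45),
                          meanlog_a = log(0.05), sdlog_a = 0.45,
                          meanlog_b = log(0.25), sdlog_b = 0.85,
                          supp_month1_a = 0.15, supp_month1_b = 0.65,
                          supp_surgical = 0.7, supp_sdlog = 0.6,
                          hazard_pepi0 = 0, hazard_gt10 = 0.008,
                          hazard_le10 = 0.002,
                          censoring_rate = 0.1,
                          fu_min = 36, fu_max = 84,
                          pt_probs = c(0.35, 0.45, 0.15, 0.05),
                          p_n0 = 0.6) {
  if (n_cases < 1) stop_ki67("n_cases must be >= 1", "ki67cta_config_error")
  if (abs(sum(luminal_weights) - 1) > 1e-8)
    stop_ki67("luminal_weights must sum to 1", "ki67cta_config_error")
  if (any(c(hazard_pepi0, hazard_gt10, hazard_le10) < 0))
    stop_ki67("hazards must be >= 0", "ki67cta_config_error")
  assert_prob(censoring_rate, "censoring_rate")
  assert_prob(p_n0, "p_n0")
  structure(as.list(environment()), class = "cohort_config")
}

# truncated log-normal draw of a Ki-67 fraction, resampled below 0.98
rtheta <- function(n, meanlog, sdlog, cap = 0.98) {
  x <- stats::rlnorm(n, meanlog, sdlog)
  while (any(bad <- x >= cap))
    x[bad] <- stats::rlnorm(sum(bad), meanlog, sdlog)
  x
}

#' Generate a synthetic patient cohort
#'
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return data frame of class `ki67_cohort` with columns case_id, pT, nodal,
#'   er_allred, luminal_label, theta_baseline/month1/surgical (true
#'   fractions), ki67_baseline/month1/surgical (percent), rfs_months,
#'   relapse_event.
#' @export
generate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(child_seed(seed, "cohort"))
  n <- config$n_cases
  lab <- sample(c("A", "B"), n, replace = TRUE, prob = config$luminal_weights)
  th0 <- ifelse(lab == "A",
                rtheta(n, config$meanlog_a, config$sdlog_a),
                rtheta(n, config$meanlog_b, config$sdlog_b))
  s1 <- stats::rlnorm(n, log(ifelse(lab == "A", config$supp_month1_a,
                                    config$supp_month1_b)), config$supp_sdlog)
  th1 <- pmin(th0 * s1, 0.98)
  s2 <- stats::rlnorm(n, log(config$supp_surgical), config$supp_sdlog)
  th2 <- pmin(th1 * s2, 0.98)

  pT <- sample(1:4, n, replace = TRUE, prob = config$pt_probs)
  nodal <- ifelse(stats::runif(n) < config$p_n0, "N0", "N+")
  # ER loss after endocrine therapy co-occurs with high residual Ki-67 or
  # high stage, so modified-PEPI-0 cases are always ER+ (Allred 3-8)
  high_risk <- th2 > 0.10 | pT >= 3
  er <- sample(3:8, n, replace = TRUE, prob = c(1, 1, 2, 3, 4, 4))
  lose <- high_risk & stats::runif(n) < 0.10
  er[lose] <- sample(0:2, sum(lose), replace = TRUE)

  mp0 <- pT <= 2 & nodal == "N0" & 100 * th2 <= 2.7
  hz <- ifelse(mp0, config$hazard_pepi0,
               ifelse(100 * th1 > 10, config$hazard_gt10, config$hazard_le10))
  t_ev <- ifelse(hz > 0, stats::rexp(n, pmax(hz, 1e-12)), Inf)
  cens <- stats::runif(n, config$fu_min, config$fu_max)
  # drop-out censoring strikes before the event by construction, so
  # censoring_rate = 1 censors every record
  drop <- stats::runif(n) < config$censoring_rate
  cens[drop] <- stats::runif(sum(drop)) * pmin(t_ev, cens)[drop]
  ev <- t_ev <= cens
  rfs <- pmin(t_ev, cens)

  out <- data.frame(case_id = sprintf("case_%04d", seq_len(n)),
                    pT = pT, nodal = nodal, er_allred = er,
                    luminal_label = lab,
                    theta_baseline = th0, theta_month1 = th1,
                    theta_surgical = th2,
                    ki67_baseline = 100 * th0,
                    ki67_month1 = 100 * th1,
                    ki67_surgical = 100 * th2,
                    rfs_months = rfs, relapse_event = ev,
                    stringsAsFactors = FALSE)
  class(out) <- c("ki67_cohort", "data.frame")
  attr(out, "provenance") <- provenance(seed, unclass(config))
  out
}

#' Rater noise model
#'
#' A rater's score for a case with true positive fraction theta is
#' `100 * Binomial(n_cells, plogis(qlogis(theta) + eps)) / n_cells` with
#' field-selection noise `eps ~ Normal(0, sigma_field)`, independent between
#' raters. Exact endpoints theta = 0 or 1 are propagated exactly.
#'
#' @param sigma_field SD of logit-scale field-selection noise; default 0.25
#'   is calibrated so two raters on the default luminal mixture have mean
#'   Spearman correlation inside the 0.85-0.95 band.
#' @param cells_counted expected cells counted per case (>= 200 by default).
#' @return object of class `rater_model`.
#' @export
rater_model <- function(sigma_field = 0.25, cells_counted = 300) {
  if (sigma_field < 0) stop_ki67("sigma_field must be >= 0",
                                 "ki67cta_config_error")
  if (cells_counted < 1) stop_ki67("cells_counted must be >= 1",
                                   "ki67cta_config_error")
  structure(list(sigma_field = sigma_field, cells_counted = cells_counted),
            class = "rater_model")
}

#' Generate paired blinded-rater scores
#'
#' @param theta vector of true Ki-67 fractions in \[0,1\], one per case.
#' @param model_a,model_b [rater_model()]s for the two raters.
#' @param seed integer seed.
#' @param case_id optional ids.
#' @return data frame of class `paired_scores` with case_id, score_a,
#'   score_b (percent).
#' @export
generate_paired_scores <- function(theta, model_a, model_b, seed,
                                   case_id = NULL) {
  stopifnot(inherits(model_a, "rater_model"), inherits(model_b, "rater_model"))
  if (any(theta < 0 | theta > 1)) stop_ki67("theta must be in [0,1]",
                                            "ki67cta_config_error")
  one <- function(model, which) {
    set.seed(child_seed(seed, paste0("rater_", which)))
    n <- length(theta)
    eps <- stats::rnorm(n, 0, model$sigma_field)
    p <- ifelse(theta %in% c(0, 1), theta,
                stats::plogis(stats::qlogis(theta) + eps))
    100 * stats::rbinom(n, model$cells_counted, p) / model$cells_counted
  }
  out <- data.frame(case_id = case_id %||% sprintf("case_%04d",
                                                   seq_along(theta)),
                    score_a = one(model_a, "a"),
                    score_b = one(model_b, "b"),
                    stringsAsFactors = FALSE)
  class(out) <- c("paired_scores", "data.frame")
  attr(out, "provenance") <- provenance(seed, list(a = unclass(model_a),
                                                   b = unclass(model_b)))
  out
}
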