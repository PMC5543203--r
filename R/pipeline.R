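#' Case-mix probabilities for the confounder scenarios
#'
#' Per-case probabilities of the four algorithm-failure scenarios.
#' Independent draws give P(any flag) = 1 - 0.92*0.96*0.97*0.97 ~ 0.169,
#' the calibrated ~17% VPC triage rate.
#'
#' @param p_lymphocyte_rich,p_streaming,p_fibroblast_marking,p_faint_stain
#'   scenario probabilities.
#' @return named list.
#' @export
case_mix <- function(p_lymphocyte_rich = 0.08, p_streaming = 0.04,
                     p_fibroblast_marking = 0.03, p_faint_stain = 0.03) {
  for (p in c(p_lymphocyte_rich, p_streaming, p_fibroblast_marking,
              p_faint_stain)) assert_prob(p, "case mix probability")
  as.list(environment())
}

#' Draw a per-case histology configuration
#'
#' Scenario indicators are drawn from the case mix; scenario-affected
#' parameters land beyond their triage thresholds (e.g. a lymphocyte-rich
#' case draws an infiltration level pushing the lymphocyte fraction past
#' 0.3), normal cases stay clear of them.
#'
#' @param theta true Ki-67 fraction for the case.
#' @param seed integer seed.
#' @param mix a [case_mix()].
#' @param ... passed through to [histology_config()].
#' @return a `histology_config`.
#' @export
draw_case_histology <- function(theta, seed, mix = case_mix(), ...) {
  set.seed(child_seed(seed, "case_histology"))
  lymph_rich <- stats::runif(1) < mix$p_lymphocyte_rich
  streaming <- stats::runif(1) < mix$p_streaming
  fib_mark <- stats::runif(1) < mix$p_fibroblast_marking
  faint <- stats::runif(1) < mix$p_faint_stain
  histology_config(
    lymphocyte_infiltration_level =
      if (lymph_rich) stats::runif(1, 0.3, 0.7) else stats::runif(1, 0, 0.15),
    streaming_prob = as.numeric(streaming),
    fibroblast_stained_frac =
      if (fib_mark) stats::runif(1, 0.25, 0.5) else stats::runif(1, 0, 0.12),
    stain_contrast =
      if (faint) stats::runif(1, 0.1, 0.25) else stats::runif(1, 0.6, 1),
    theta = theta, ...)
}

#' Full pipeline configuration
#'
#' @param seed global seed; all component seeds derive from it via
#'   [child_seed()].
#' @param cohort a [cohort_config()].
#' @param thresholds a [triage_thresholds()].
#' @param grid a [grid_spec()].
#' @param mix a [case_mix()].
#' @param cutpoints Ki-67 cut-points in percent (default 2.7 and 10).
#' @param n_vpc_fields fields generated per VPC-routed case.
#' @param rater_sigma logit-scale rater noise for the month-1 score model;
#'   0 makes both raters identical.
#' @param rater_cells cells counted by the month-1 score model.
#' @param rater_jitter jitter AOI grids between raters (FALSE makes the two
#'   raters score image-routed cases identically).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, cohort = cohort_config(),
                            thresholds = triage_thresholds(),
                            grid = grid_spec(), mix = case_mix(),
                            cutpoints = c(2.7, 10),
                            n_vpc_fields = 10,
                            rater_sigma = 0.25, rater_cells = 300,
                            rater_jitter = TRUE) {
  if (any(cutpoints <= 0 | cutpoints >= 100))
    stop_ki67("cutpoints must be in (0, 100)", "ki67cta_config_error")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full synthetic validation pipeline
#'
#' simulate cohort -> per-case histology -> two-rater SOP scoring of the
#' surgical specimen -> month-1 paired scores -> agreement statistics at
#' each cut-point -> PEPI classification -> Kaplan-Meier / log-rank per
#' stratum -> REMARK flow. Deterministic for a fixed config seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, scores/summary/flow are
#'   written (CSV + JSON with provenance).
#' @return list: cohort (with PEPI columns), sop (per-case routes/scores for
#'   both raters), agreement (Table-1-shaped rows), survival (KM + log-rank
#'   per stratification), flow (`remark_flow`), triage_rate, provenance.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  cohort <- generate_cohort(config$cohort, seed)
  n <- nrow(cohort)

  route_a <- character(n); route_b <- character(n)
  surg_a <- numeric(n); surg_b <- numeric(n)
  flags_any <- logical(n)
  excluded <- character(0)
  for (i in seq_len(n)) {
    cs <- child_seed(seed, "case", i)
    hcfg <- draw_case_histology(cohort$theta_surgical[i], cs, config$mix)
    slide <- generate_cellmap(hcfg, child_seed(cs, "slide"))
    maps <- list(slide)
    pre <- triage_flags(map_statistics(slide), config$thresholds)
    flags_any[i] <- pre$route == "VPC"
    if (pre$route == "VPC")
      for (k in seq_len(config$n_vpc_fields - 1L))
        maps[[k + 1L]] <- generate_cellmap(hcfg, child_seed(cs, "field", k))
    img <- if (pre$route == "IMAGE") render_field(slide) else NULL
    res <- lapply(c(a = 1L, b = 2L), function(r) {
      rseed <- child_seed(cs, "rater", r)
      if (!config$rater_jitter) rseed <- child_seed(cs, "rater", 1L)
      tryCatch(
        sop_score(maps, case_id = cohort$case_id[i],
                  thresholds = config$thresholds, spec = config$grid,
                  seed = rseed, rater_jitter = config$rater_jitter,
                  image = img),
        ki67cta_undefined_score = function(e) NULL)
    })
    if (is.null(res$a) || is.null(res$b)) {
      excluded <- c(excluded, cohort$case_id[i])
      route_a[i] <- route_b[i] <- "EXCLUDED"
      surg_a[i] <- surg_b[i] <- NA_real_
      next
    }
    route_a[i] <- res$a$route; route_b[i] <- res$b$route
    surg_a[i] <- res$a$score$percent; surg_b[i] <- res$b$score$percent
  }

  sop <- data.frame(case_id = cohort$case_id,
                    route_a = route_a, route_b = route_b,
                    score_a = surg_a, score_b = surg_b,
                    triage_flagged = flags_any,
                    stringsAsFactors = FALSE)

  m1 <- generate_paired_scores(cohort$theta_month1,
                               rater_model(config$rater_sigma,
                                           config$rater_cells),
                               rater_model(config$rater_sigma,
                                           config$rater_cells),
                               child_seed(seed, "month1"),
                               case_id = cohort$case_id)

  keep <- route_a != "EXCLUDED"
  surg_pairs <- data.frame(case_id = cohort$case_id[keep],
                           score_a = surg_a[keep], score_b = surg_b[keep])
  agreement <- c(
    lapply(config$cutpoints, function(cp)
      agreement_row(surg_pairs, cp, method = "SOP",
                    sample_set = "surgical")),
    list(agreement_row(m1, 10, method = "rater-model",
                       sample_set = "month1")))

  cohort <- classify_pepi(cohort)
  surv <- list(
    modified_pepi0 = km_by(cohort, cohort$modified_pepi0,
                           c("non-0", "modified-PEPI-0")),
    month1_gt10 = km_by(cohort, cohort$ki67_month1 > 10,
                        c("le10", "gt10")))
  # score-based PEPI from rater A's SOP score (surgical specimen)
  mp0_a <- modified_pepi0(cohort$pT, cohort$nodal, sop$score_a)
  surv$modified_pepi0_rater_a <-
    km_by(cohort[keep, ], mp0_a[keep], c("non-0", "modified-PEPI-0"))

  flow <- remark_flow(list(
    list(stage = "simulated", n_in = n, excluded = integer(0)),
    list(stage = "sop_scored", n_in = n,
         excluded = c(no_tumor = length(excluded))),
    list(stage = "concordance", n_in = n - length(excluded),
         excluded = integer(0))))

  out <- list(cohort = cohort, sop = sop, month1_pairs = m1,
              agreement = agreement, survival = surv, flow = flow,
              triage_rate = mean(flags_any),
              excluded = excluded,
              provenance = provenance(seed, list(hash = "pipeline")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_csv_prov(cohort, file.path(out_dir, "cohort.csv"),
                   attr(cohort, "provenance"))
    write_csv_prov(sop, file.path(out_dir, "sop_scores.csv"),
                   out$provenance)
    jsonlite::write_json(
      list(agreement = agreement,
           survival = summarize_survival(surv),
           triage_rate = out$triage_rate,
           flow = flow$table, provenance = out$provenance),
      file.path(out_dir, "summary.json"),
      auto_unbox = TRUE, digits = 10, pretty = TRUE)
  }
  out
}

km_by <- function(cohort, strat, labels) {
  strat <- factor(ifelse(strat, labels[2], labels[1]), levels = labels)
  curves <- lapply(levels(strat), function(l) {
    idx <- strat == l
    if (!any(idx)) return(NULL)
    km_estimate(cohort$rfs_months[idx], cohort$relapse_event[idx])
  })
  names(curves) <- levels(strat)
  lr <- if (all(table(strat) > 0))
    logrank(cohort$rfs_months, cohort$relapse_event, strat) else NULL
  events <- tapply(cohort$relapse_event, strat, sum)
  list(curves = curves, logrank = lr,
       n = as.list(table(strat)), events = as.list(events))
}

summarize_survival <- function(surv) {
  lapply(surv, function(s)
    list(n = s$n, events = s$events,
         logrank_chisq = if (!is.null(s$logrank)) s$logrank$chisq else NA,
         logrank_p = if (!is.null(s$logrank)) s$logrank$p_value else NA))
}

#' REMARK-style flow accounting
#'
#' Each stage carries cases in, named exclusion counts with reasons, and
#' implies cases out; conservation (in = out + excluded) is enforced and a
#' violation is a hard error, since it indicates a silent drop.
#'
#' @param stages list of `list(stage, n_in, excluded = named integer)`.
#' @return object of class `remark_flow` with a stage table.
#' @export
remark_flow <- function(stages) {
  rows <- lapply(stages, function(s) {
    excl <- sum(s$excluded)
    n_out <- s$n_out %||% (s$n_in - excl)
    if (s$n_in - excl != n_out)
      stop_ki67(sprintf("flow conservation violated at stage '%s'", s$stage),
                "ki67cta_flow_error")
    data.frame(stage = s$stage, n_in = s$n_in, n_excluded = excl,
               reasons = paste(sprintf("%s=%d", names(s$excluded),
                                       s$excluded), collapse = ";"),
               n_out = n_out, stringsAsFactors = FALSE)
  })
  structure(list(table = do.call(rbind, rows)), class = "remark_flow")
}

#' @export
print.remark_flow <- function(x, ...) {
  print(x$table)
  invisible(x)
}
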