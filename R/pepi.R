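#' Classify a Ki-67 value against a cut-point
#'
#' The boundary is inclusive on the favorable side: a value equal to the
#' cut-point is called `at_or_below`.
#'
#' @param value Ki-67 percent in \[0,100\]; NA propagates as undetermined.
#' @param cutpoint percent (2.7 and 10 are the clinically used values).
#' @return object of class `cutpoint_call`: value, cutpoint, call
#'   ("at_or_below", "above" or "undetermined").
#' @export
classify_cutpoint <- function(value, cutpoint) {
  stopifnot(cutpoint > 0, cutpoint < 100)
  if (length(value) > 1)
    return(lapply(value, classify_cutpoint, cutpoint = cutpoint))
  call <- if (is.na(value)) "undetermined"
          else if (value < 0 || value > 100)
            stop_ki67("Ki-67 value outside [0,100]", "ki67cta_config_error")
          else if (value <= cutpoint) "at_or_below" else "above"
  structure(list(value = value, cutpoint = cutpoint, call = call),
            class = "cutpoint_call")
}

# vectorized helper: TRUE / FALSE / NA for at-or-below
at_or_below <- function(value, cutpoint) {
  ifelse(is.na(value), NA, value <= cutpoint)
}

#' Modified PEPI-0 status (ER-free rule)
#'
#' TRUE iff pathological stage pT1/2, node-negative, and surgical Ki-67 at
#' or below 2.7%. The ER-free modification supports trials using ER
#' down-regulators, where post-treatment ER levels are uninterpretable.
#'
#' @param pT integer 1-4 (or "pT1".."pT4").
#' @param nodal "N0" or "N+".
#' @param ki67_surgical percent.
#' @param cutpoint default 2.7.
#' @return logical (NA when any component is missing). Vectorized.
#' @export
modified_pepi0 <- function(pT, nodal, ki67_surgical, cutpoint = 2.7) {
  pT <- as.integer(sub("^pT", "", as.character(pT)))
  ifelse(is.na(pT) | is.na(nodal) | is.na(ki67_surgical), NA,
         pT <= 2 & nodal == "N0" & ki67_surgical <= cutpoint)
}

#' PEPI-0 status (with ER persistence)
#'
#' TRUE iff [modified_pepi0()] and the surgical ER Allred score is 3-8
#' (ER retained). Missing ER leaves PEPI-0 undetermined while modified
#' PEPI-0 remains decidable.
#'
#' @inheritParams modified_pepi0
#' @param er_allred integer 0-8.
#' @return logical (NA when undetermined). Vectorized.
#' @export
pepi0 <- function(pT, nodal, ki67_surgical, er_allred, cutpoint = 2.7) {
  if (any(!is.na(er_allred) & (er_allred < 0 | er_allred > 8)))
    stop_ki67("er_allred must be in 0..8", "ki67cta_config_error")
  mp0 <- modified_pepi0(pT, nodal, ki67_surgical, cutpoint)
  ifelse(is.na(mp0), NA,
         ifelse(!mp0, FALSE,
                ifelse(is.na(er_allred), NA, er_allred >= 3)))
}

#' Add PEPI columns to a cohort table
#'
#' @param cohort data frame with pT, nodal, ki67_surgical, er_allred.
#' @return the cohort with logical columns modified_pepi0 and pepi0.
#' @export
classify_pepi <- function(cohort) {
  cohort$modified_pepi0 <- modified_pepi0(cohort$pT, cohort$nodal,
                                          cohort$ki67_surgical)
  cohort$pepi0 <- pepi0(cohort$pT, cohort$nodal, cohort$ki67_surgical,
                        cohort$er_allred)
  cohort
}
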