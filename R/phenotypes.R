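# Dichotomization of NCI-CTC toxicity grades into the four analysis outcomes.
#
# DMN: diarrhoea/mucositis/neutropenia, grade 0-2 vs 3-4, all patients.
# DM:  diarrhoea/mucositis, grade 0-2 vs 3-4, Capecitabine subgroup.
# HFS: hand-and-foot syndrome, grade 0-1 vs 2-3, Capecitabine subgroup.
# sHFS: hand-and-foot syndrome, grade 0-2 vs 3, Capecitabine subgroup.
# Multi-symptom outcomes use the maximum grade over their constituent
# symptoms ("any severe constituent" convention); grade-4 HFS, never
# observed clinically, would count as affected for both HFS outcomes.

OUTCOME_NAMES <- c("DMN", "DM", "HFS", "sHFS")

#' Definition of a dichotomized toxicity outcome
#'
#' @param name One of `"DMN"`, `"DM"`, `"HFS"`, `"sHFS"`.
#' @return A list with `name`, constituent `symptoms`, the set of
#'   `affected_grades`, and the treatment `subgroup` the outcome applies to
#'   (`"all"` or `"Capecitabine"`).
#' @export
outcome_definition <- function(name) {
  switch(name,
    DMN  = list(name = "DMN",
                symptoms = c("diarrhoea", "mucositis", "neutropenia"),
                affected_grades = 3:4, subgroup = "all"),
    DM   = list(name = "DM", symptoms = c("diarrhoea", "mucositis"),
                affected_grades = 3:4, subgroup = "Capecitabine"),
    HFS  = list(name = "HFS", symptoms = "hfs",
                affected_grades = 2:4, subgroup = "Capecitabine"),
    sHFS = list(name = "sHFS", symptoms = "hfs",
                affected_grades = 3:4, subgroup = "Capecitabine"),
    stop("unknown outcome: ", name,
         " (expected one of ", paste(OUTCOME_NAMES, collapse = ", "), ")")
  )
}

#' Dichotomize toxicity grades into a binary outcome
#'
#' Samples outside the outcome's treatment subgroup are `"excluded"` (not
#' unaffected); samples with any constituent grade unrecorded are
#' `"missing"`. Otherwise a sample is `"affected"` when the maximum grade
#' over the outcome's symptoms falls in the affected-grade set.
#'
#' @param grades A `grade_table`.
#' @param outcome Outcome name or an [outcome_definition()].
#' @return Named character vector (`sample_id` -> status) with levels
#'   affected / unaffected / excluded / missing.
#' @export
dichotomize <- function(grades, outcome) {
  if (is.character(outcome)) outcome <- outcome_definition(outcome)
  g <- as.matrix(grades[, outcome$symptoms, drop = FALSE])
  status <- rep("unaffected", nrow(grades))
  maxg <- apply(g, 1L, function(r) if (anyNA(r)) NA_integer_ else max(r))
  status[!is.na(maxg) & maxg %in% outcome$affected_grades] <- "affected"
  status[is.na(maxg)] <- "missing"
  if (outcome$subgroup != "all")
    status[grades$treatment != outcome$subgroup] <- "excluded"
  names(status) <- grades$sample_id
  status
}

#' Cohort characteristics per outcome
#'
#' One row per outcome, mirroring a cohort-characteristics table: affected
#' and unaffected counts, with percent male and mean (sd) age when the
#' grade table carries `sex` (1 = male) and `age`.
#'
#' @param grades A `grade_table`.
#' @param outcomes Outcome names to summarize.
#' @return A data frame.
#' @export
outcome_summary <- function(grades, outcomes = OUTCOME_NAMES) {
  rows <- lapply(outcomes, function(nm) {
    st <- dichotomize(grades, nm)
    one <- function(lab) {
      i <- which(st == lab)
      data.frame(
        n = length(i),
        pct_male = if (!is.null(grades$sex))
          round(100 * mean(grades$sex[i] == 1L, na.rm = TRUE), 1)
          else NA_real_,
        mean_age = if (!is.null(grades$age))
          round(mean(grades$age[i], na.rm = TRUE), 1) else NA_real_,
        sd_age = if (!is.null(grades$age))
          round(stats::sd(grades$age[i], na.rm = TRUE), 1) else NA_real_
      )
    }
    aff <- one("affected"); una <- one("unaffected")
    data.frame(outcome = nm,
               affected_n = aff$n, affected_pct_male = aff$pct_male,
               affected_mean_age = aff$mean_age, affected_sd_age = aff$sd_age,
               unaffected_n = una$n, unaffected_pct_male = una$pct_male,
               unaffected_mean_age = una$mean_age,
               unaffected_sd_age = una$sd_age,
               excluded_n = sum(st == "excluded"),
               missing_n = sum(st == "missing"))
  })
  do.call(rbind, rows)
}
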