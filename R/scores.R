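# Derived clinical variables: composite cognition, NPI-4 estimate, LBD
# symptom composite, vascular-risk total, SVD burden, inclusion filters.

z_score <- function(x, ref) {
  if (is.null(ref$mean) || is.null(ref$sd) || ref$sd <= 0) {
    stop("reference stats need mean and sd > 0")
  }
  (x - ref$mean) / ref$sd
}

#' Reference statistics for z-scoring
#'
#' Builds per-component means/SDs from a reference sample — by convention the
#' control group, the usual normative choice in neuropsychology; a
#' full-sample reference is available via `reference = "all"`.
#'
#' @param cohort data.frame containing the component columns.
#' @param components character vector of column names.
#' @param reference `"control"` (rows with `group == "control"`) or `"all"`.
#' @return named list of `list(mean =, sd =)` per component.
#' @export
reference_stats <- function(cohort, components,
                            reference = c("control", "all")) {
  reference <- match.arg(reference)
  d <- if (reference == "control") {
    cohort[cohort$group == "control", , drop = FALSE]
  } else cohort
  out <- lapply(components, function(cmp) {
    x <- d[[cmp]]
    if (is.null(x)) stop("component column missing: ", cmp)
    list(mean = mean(x, na.rm = TRUE), sd = stats::sd(x, na.rm = TRUE))
  })
  names(out) <- components
  out
}

#' Composite cognitive score
#'
#' z-scored average of global cognition (MoCA) plus one task per cognitive
#' domain: Stroop colour naming (attention; timed, seconds), category
#' fluency (executive), letter fluency (language) and the Hooper visual
#' organization test (visuospatial). Timed components are sign-flipped so
#' the composite is higher-is-better throughout.
#'
#' @param record named list / one-row data.frame with fields `moca`,
#'   `stroop_colour`, `fluency_category`, `fluency_letter`, `hooper`.
#' @param reference_stats per-component `list(mean =, sd =)` as from
#'   [reference_stats()].
#' @param timed_components component names scored in seconds (lower is
#'   better), sign-flipped after z-scoring.
#' @param policy `"require_all"` (any missing component gives NA) or
#'   `"available"` (average over non-missing components).
#' @return scalar z-units; NA with a `reason` attribute when undefined.
#' @export
composite_cognitive_score <- function(record, reference_stats,
                                      timed_components = "stroop_colour",
                                      policy = c("require_all",
                                                 "available")) {
  policy <- match.arg(policy)
  components <- names(reference_stats)
  zs <- vapply(components, function(cmp) {
    x <- record[[cmp]]
    if (is.null(x) || is.na(x)) return(NA_real_)
    z <- z_score(x, reference_stats[[cmp]])
    if (cmp %in% timed_components) -z else z
  }, 1.0)
  if (all(is.na(zs))) {
    out <- NA_real_
    attr(out, "reason") <- "all components missing"
    return(out)
  }
  if (policy == "require_all" && any(is.na(zs))) {
    out <- NA_real_
    attr(out, "reason") <- paste("missing:",
                                 paste(components[is.na(zs)], collapse = ", "))
    return(out)
  }
  mean(zs, na.rm = TRUE)
}

#' NPI-4 estimate from available instruments
#'
#' The four-item Neuropsychiatric Inventory is approximated from whichever
#' mapped instruments a record carries (e.g. HADS or PHQ-9 for mood, the
#' UMPDHQ for hallucinations, UPDRS-I items). The item-level mapping is a
#' runtime configuration: a list of items, each
#' `list(fields = c(primary, fallback, ...), weight = 1)`; the first
#' non-missing field feeds the item and the provenance records which one.
#'
#' @param record named list / one-row data.frame.
#' @param mapping_config list of item mappings as above.
#' @return scalar score with attribute `provenance` (field used per item).
#' @export
npi4_estimate <- function(record, mapping_config) {
  known <- names(record)
  referenced <- unique(unlist(lapply(mapping_config, `[[`, "fields")))
  absent <- setdiff(referenced, known)
  if (length(absent) > 0) {
    stop("mapping references absent fields: ", paste(absent, collapse = ", "))
  }
  used <- character(length(mapping_config))
  total <- 0
  for (i in seq_along(mapping_config)) {
    item <- mapping_config[[i]]
    w <- item$weight %||% 1
    val <- NA_real_
    for (f in item$fields) {
      x <- record[[f]]
      if (!is.null(x) && !is.na(x)) { val <- x; used[i] <- f; break }
    }
    if (is.na(val)) {
      out <- NA_real_
      attr(out, "provenance") <- used
      return(out)
    }
    total <- total + w * val
  }
  attr(total, "provenance") <- used
  total
}

#' Lewy-body symptom composite
#'
#' Severity-aligned z-average of the NPI-4 estimate, UPDRS-III, the dementia
#' cognitive fluctuation scale and MoCA; MoCA is sign-flipped so that a
#' higher composite means worse symptoms. All four components must be
#' present.
#'
#' @param npi4,updrs3,dcfs,moca component values.
#' @param reference_stats list with elements `npi4`, `updrs3`, `dcfs`,
#'   `moca`, each `list(mean =, sd =)`.
#' @param zscore if FALSE, average severity-aligned raw values instead.
#' @return scalar z-units (or raw average); NA if any component missing.
#' @export
lbd_symptom_composite <- function(npi4, updrs3, dcfs, moca, reference_stats,
                                  zscore = TRUE) {
  vals <- c(npi4 = npi4, updrs3 = updrs3, dcfs = dcfs, moca = moca)
  if (any(is.na(vals))) return(NA_real_)
  if (zscore) {
    zs <- vapply(names(vals), function(nm)
      z_score(vals[[nm]], reference_stats[[nm]]), 1.0)
    zs["moca"] <- -zs["moca"]
    mean(zs)
  } else {
    vals["moca"] <- -vals["moca"]
    mean(vals)
  }
}

#' Vascular-risk factor total
#'
#' Count of positive items among the seven self-reported vascular risk
#' factors: angina, myocardial infarction, stroke, diabetes, high
#' cholesterol, high blood pressure, smoking. Range 0-7.
#'
#' @param items logical vector of length 7 (named or not).
#' @param na_action `"error"` or `"na"`.
#' @return integer in 0..7.
#' @export
vascular_risk_score <- function(items, na_action = c("error", "na")) {
  na_action <- match.arg(na_action)
  if (length(items) != 7) stop("expected 7 vascular-risk items")
  if (any(is.na(items))) {
    if (na_action == "error") stop("missing vascular-risk item")
    return(NA_integer_)
  }
  as.integer(sum(as.logical(items)))
}

#' Total small-vessel-disease burden score
#'
#' One point for each MRI feature of SVD: at least one lacune, at least one
#' cerebral microbleed, moderate-to-severe (grade 2-4) enlarged perivascular
#' spaces in the basal ganglia, and modified Fazekas score 2 or 3.
#' Range 0-4.
#'
#' @param fazekas modified Fazekas rating, integer 0-3.
#' @param cmb_count cerebral microbleed count (>= 0).
#' @param lacune_count lacune count (>= 0).
#' @param epvs_grade basal-ganglia EPVS grade, integer 0-4.
#' @return integer in 0..4.
#' @export
svd_burden <- function(fazekas, cmb_count, lacune_count, epvs_grade) {
  if (is.na(fazekas) || fazekas < 0 || fazekas > 3) {
    stop("Fazekas rating out of range [0, 3]: ", fazekas)
  }
  if (is.na(epvs_grade) || epvs_grade < 0 || epvs_grade > 4) {
    stop("EPVS grade out of range [0, 4]: ", epvs_grade)
  }
  if (is.na(cmb_count) || cmb_count < 0 || is.na(lacune_count) ||
      lacune_count < 0) {
    stop("microbleed / lacune counts must be >= 0")
  }
  as.integer((lacune_count >= 1) + (cmb_count >= 1) +
               (epvs_grade >= 2) + (fazekas >= 2))
}

#' Cohort inclusion filters
#'
#' Removes controls with MMSE below the cutoff and patients more than
#' `max_duration` years from diagnosis (PDD measured from the dementia
#' diagnosis when a `duration_dementia` column is present). "Within 10
#' years" is read inclusively: exactly 10 years is retained. Idempotent.
#'
#' @param cohort data.frame with `group`, `mmse` and `duration` columns
#'   (years since diagnosis); optional `duration_dementia` for PDD.
#' @param mmse_cutoff minimum control MMSE (default 25; controls below it
#'   are excluded).
#' @param max_duration maximum years since diagnosis for patients
#'   (default 10, inclusive).
#' @return list with `cohort` (retained rows) and `log` (data.frame of
#'   exclusions: row index, id if present, rule).
#' @export
apply_inclusion_filters <- function(cohort, mmse_cutoff = 25,
                                    max_duration = 10) {
  if (nrow(cohort) == 0) {
    return(list(cohort = cohort,
                log = data.frame(row = integer(), id = character(),
                                 rule = character())))
  }
  is_control <- cohort$group == "control"
  drop_mmse <- is_control & !is.na(cohort$mmse) & cohort$mmse < mmse_cutoff
  rel_dur <- cohort$duration
  if ("duration_dementia" %in% names(cohort)) {
    use_dem <- cohort$group == "PDD" & !is.na(cohort$duration_dementia)
    rel_dur[use_dem] <- cohort$duration_dementia[use_dem]
  }
  drop_dur <- !is_control & !is.na(rel_dur) & rel_dur > max_duration
  rule <- ifelse(drop_mmse, "control_mmse_lt_cutoff",
                 ifelse(drop_dur, "duration_gt_max", NA))
  drop <- drop_mmse | drop_dur
  log <- data.frame(row = which(drop),
                    id = if ("id" %in% names(cohort)) {
                      cohort$id[drop]
                    } else as.character(which(drop)),
                    rule = rule[drop], stringsAsFactors = FALSE)
  list(cohort = cohort[!drop, , drop = FALSE], log = log)
}
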