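#' Default cohort group specifications
#'
#' Four diagnostic groups mirroring a Lewy-body-dementia imaging cohort:
#' age-matched controls, Parkinson's with normal cognition (PD-NC),
#' Parkinson's disease dementia (PDD) and dementia with Lewy bodies (DLB).
#' Group sizes, age structure and sex ratios follow published Lewy-body
#' imaging cohorts of this design (26 / 60 / 35 / 51); ALPS means are set so
#' that the between-group standardized differences reproduce the reported
#' ordering (control ~ PD-NC > PDD > DLB) with a common residual SD of 0.14.
#' Clinical means/SDs (MoCA, MMSE, UPDRS-III) are typical of such cohorts.
#'
#' @return named list of per-group spec lists.
#' @export
default_group_specs <- function() {
  list(
    control = list(n = 26L, alps_mean = 1.496, alps_sd = 0.14,
                   age_mean = 66.7, age_sd = 9.28, male_prop = 0.5,
                   moca_mean = 28.8, moca_sd = 1.3,
                   mmse_mean = 29.1, mmse_sd = 1.0,
                   updrs3_mean = 5.65, updrs3_sd = 4.8,
                   complexity_mean = 0.45, complexity_sd = 0.05),
    `PD-NC` = list(n = 60L, alps_mean = 1.500, alps_sd = 0.14,
                   age_mean = 63.1, age_sd = 7.33, male_prop = 27 / 60,
                   moca_mean = 28.7, moca_sd = 1.2,
                   mmse_mean = 29.3, mmse_sd = 0.8,
                   updrs3_mean = 19.9, updrs3_sd = 10.1,
                   complexity_mean = 0.45, complexity_sd = 0.05),
    PDD = list(n = 35L, alps_mean = 1.420, alps_sd = 0.14,
               age_mean = 69.5, age_sd = 7.8, male_prop = 25 / 35,
               moca_mean = 24.5, moca_sd = 4.2,
               mmse_mean = 27.7, mmse_sd = 2.5,
               updrs3_mean = 30.6, updrs3_sd = 13.2,
               complexity_mean = 0.42, complexity_sd = 0.05),
    DLB = list(n = 51L, alps_mean = 1.319, alps_sd = 0.14,
               age_mean = 72.7, age_sd = 5.5, male_prop = 43 / 51,
               moca_mean = 20.6, moca_sd = 5.2,
               mmse_mean = 23.5, mmse_sd = 4.0,
               updrs3_mean = 36.4, updrs3_sd = 18.0,
               complexity_mean = 0.42, complexity_sd = 0.05)
  )
}

#' Simulate a clinical cohort with known ground truth
#'
#' Draws a per-participant table with group, age, sex, ALPS, complexity and
#' clinical columns. The ALPS value is built as
#' `group mean + beta_age * (age - 70) + beta_sex * male + N(0, alps_sd)`,
#' so the group-spec means are the covariate-adjusted ground truth and
#' `alps_sd` is the residual SD. Requested group sizes are respected exactly
#' and the draw is fully determined by `seed`.
#'
#' @param group_specs named list as from [default_group_specs()]; each entry
#'   needs at least `n`, `alps_mean`, `alps_sd`, `age_mean`, `age_sd`,
#'   `male_prop`.
#' @param covariate_model list with `beta_age` and `beta_sex` (effects on
#'   ALPS per year and for male sex; default 0 each).
#' @param seed integer seed.
#' @return `data.frame` with columns `id`, `group` (factor, spec order),
#'   `age`, `sex` (factor M/F), `alps`, `complexity`, plus `moca`, `mmse`,
#'   `updrs3` when the specs carry those means.
#' @export
simulate_cohort <- function(group_specs = default_group_specs(),
                            covariate_model = list(beta_age = 0,
                                                   beta_sex = 0),
                            seed = 1L) {
  for (nm in names(group_specs)) {
    gs <- group_specs[[nm]]
    if (gs$n < 2) stop("group ", nm, ": n must be >= 2")
    sds <- unlist(gs[grepl("_sd$", names(gs))])
    if (any(sds < 0)) stop("group ", nm, ": negative SD")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  beta_age <- covariate_model$beta_age %||% 0
  beta_sex <- covariate_model$beta_sex %||% 0
  rows <- lapply(names(group_specs), function(nm) {
    gs <- group_specs[[nm]]
    n <- gs$n
    age <- stats::rnorm(n, gs$age_mean, gs$age_sd)
    n_male <- round(gs$male_prop * n)
    sex <- sample(rep(c("M", "F"), c(n_male, n - n_male)))
    male <- as.numeric(sex == "M")
    alps <- gs$alps_mean + beta_age * (age - 70) + beta_sex * male +
      stats::rnorm(n, 0, gs$alps_sd)
    d <- data.frame(group = nm, age = age, sex = sex, alps = alps,
                    stringsAsFactors = FALSE)
    opt <- function(field) {
      mu <- gs[[paste0(field, "_mean")]]
      if (is.null(mu)) return(NULL)
      stats::rnorm(n, mu, gs[[paste0(field, "_sd")]] %||% 0)
    }
    for (f in c("complexity", "moca", "mmse", "updrs3")) {
      v <- opt(f)
      if (!is.null(v)) d[[f]] <- v
    }
    d
  })
  out <- do.call(rbind, rows)
  out$id <- sprintf("sub-%03d", seq_len(nrow(out)))
  out$group <- factor(out$group, levels = names(group_specs))
  out$sex <- factor(out$sex, levels = c("M", "F"))
  out[, c("id", setdiff(names(out), "id"))]
}
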