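# Group-comparison and regression framework: general linear model engine,
# ANCOVA omnibus and planned contrasts with covariate-adjusted Cohen's d,
# BH-FDR, nested regressions, VIF, paired hemisphere test, and the
# nonparametric table tests (Kruskal-Wallis / rank-sum with Dunn post hoc).

#' Least-squares fit of a general linear model
#'
#' Thin wrapper over `stats::lm` that performs listwise deletion, errors on
#' aliased (rank-deficient) designs naming the offending columns, and
#' returns the quantities downstream code needs.
#'
#' @param y numeric response.
#' @param design data.frame of predictors (factors allowed); an intercept is
#'   always added. `NULL` or zero columns gives the intercept-only model.
#' @return object of class `glm_fit`: `coef`, `rss`, `df_resid`, `sigma`,
#'   `fitted`, `r_squared`, `n`, `n_dropped`, and the underlying `lm`.
#' @export
fit_glm <- function(y, design = NULL) {
  if (is.null(design) || (is.data.frame(design) && ncol(design) == 0)) {
    design <- data.frame(row.names = seq_along(y))
  }
  d <- as.data.frame(design)
  d$.y <- y
  complete <- stats::complete.cases(d)
  d <- d[complete, , drop = FALSE]
  if (nrow(d) <= ncol(d)) stop("more parameters than observations")
  fml <- if (ncol(d) == 1) .y ~ 1 else
    stats::as.formula(paste(".y ~", paste(sprintf("`%s`",
      setdiff(names(d), ".y")), collapse = " + ")))
  fit <- stats::lm(fml, data = d)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; aliased columns: ",
         paste(bad, collapse = ", "))
  }
  res <- stats::residuals(fit)
  rss <- sum(res^2)
  tss <- sum((d$.y - mean(d$.y))^2)
  structure(list(coef = stats::coef(fit), rss = rss,
                 df_resid = stats::df.residual(fit),
                 sigma = sqrt(rss / stats::df.residual(fit)),
                 fitted = stats::fitted(fit),
                 r_squared = if (tss > 0) 1 - rss / tss else 0,
                 n = nrow(d), n_dropped = sum(!complete), lm = fit),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat("GLM fit: n =", x$n, " df_resid =", x$df_resid,
      " R^2 =", signif(x$r_squared, 4), "\n")
  print(signif(x$coef, 4))
  invisible(x)
}

#' Omnibus ANCOVA for a group factor
#'
#' Full-versus-reduced F test for the group factor with covariates held in
#' both models:
#' `F = ((RSS_reduced - RSS_full) / df_diff) / (RSS_full / df_resid)`.
#'
#' @param y numeric response.
#' @param group factor (>= 2 levels, each with >= 2 observations after
#'   listwise deletion).
#' @param covariates data.frame of covariates or NULL.
#' @return object of class `ancova_fit`: `F`, `df1`, `df2`, `p`, plus the
#'   two `glm_fit`s.
#' @export
ancova_omnibus <- function(y, group, covariates = NULL) {
  group <- droplevels(factor(group))
  if (nlevels(group) < 2) stop("need >= 2 groups")
  d_full <- data.frame(group = group)
  if (!is.null(covariates)) d_full <- cbind(d_full, covariates)
  # joint listwise deletion so full and reduced models see the same rows
  keep <- stats::complete.cases(cbind(d_full, y))
  if (any(table(group[keep]) < 2) || nlevels(droplevels(group[keep])) <
      nlevels(group)) {
    stop("a group has fewer than 2 complete cases after listwise deletion")
  }
  y <- y[keep]
  d_full <- d_full[keep, , drop = FALSE]
  full <- fit_glm(y, d_full)
  red <- fit_glm(y, if (is.null(covariates)) NULL else
    d_full[, -1, drop = FALSE])
  df1 <- red$df_resid - full$df_resid
  df2 <- full$df_resid
  # guard the degenerate zero-residual case (exact fits on toy data)
  ss_group <- max(red$rss - full$rss, 0)
  scale0 <- .Machine$double.eps * max(1, sum(y^2))
  Fv <- if (ss_group <= scale0) 0 else (ss_group / df1) / (full$rss / df2)
  structure(list(F = Fv, df1 = df1, df2 = df2,
                 p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
                 full = full, reduced = red),
            class = "ancova_fit")
}

#' @export
print.ancova_fit <- function(x, ...) {
  cat(sprintf("ANCOVA omnibus: F(%d, %d) = %.3f, p = %.4g\n",
              x$df1, x$df2, x$F, x$p))
  invisible(x)
}

#' Planned pairwise contrasts with covariate-adjusted effect sizes
#'
#' Each pair is tested by a two-group ANCOVA restricted to that pair with
#' the same covariates; raw p-values are jointly BH-adjusted across the
#' pairs. Cohen's d is, by default, the covariate-adjusted group-mean
#' difference divided by the pooled residual SD of the two-group model
#' (`d_method = "raw"` uses unadjusted means and the pooled raw SD).
#'
#' @param y numeric response.
#' @param group factor.
#' @param covariates data.frame or NULL.
#' @param pairs list of 2-character vectors; default: every disease group
#'   vs control plus the between-disease pairs, in group-level order.
#' @param d_method `"adjusted"` (default) or `"raw"`.
#' @return data.frame of class `contrast_table`: contrast, F, df1, df2,
#'   p, p_fdr, d, n1, n2.
#' @export
planned_contrasts <- function(y, group, covariates = NULL, pairs = NULL,
                              d_method = c("adjusted", "raw")) {
  d_method <- match.arg(d_method)
  group <- droplevels(factor(group))
  if (is.null(pairs)) {
    lev <- levels(group)
    pairs <- utils::combn(lev, 2, simplify = FALSE)
  }
  labs <- vapply(pairs, function(p) paste(sort(p), collapse = " vs "), "")
  if (anyDuplicated(labs)) stop("duplicate contrast pair")
  rows <- lapply(pairs, function(pr) {
    sel <- group %in% pr
    g2 <- droplevels(group[sel])
    y2 <- y[sel]
    cv2 <- if (is.null(covariates)) NULL else
      droplevels(as.data.frame(covariates)[sel, , drop = FALSE])
    fit <- ancova_omnibus(y2, g2, cv2)
    # adjusted difference: coefficient of the second-level indicator
    cf <- fit$full$coef
    gcoef <- cf[grep("^group", names(cf))][1]
    dval <- if (d_method == "adjusted") {
      -gcoef / fit$full$sigma          # level1 - level2 difference
    } else {
      m <- tapply(y2, g2, mean)
      s <- tapply(y2, g2, stats::var)
      n <- tapply(y2, g2, length)
      sp <- sqrt(((n[1] - 1) * s[1] + (n[2] - 1) * s[2]) / (sum(n) - 2))
      (m[1] - m[2]) / sp
    }
    data.frame(contrast = paste(levels(g2), collapse = " vs "),
               F = fit$F, df1 = fit$df1, df2 = fit$df2, p = fit$p,
               d = as.numeric(dval),
               n1 = sum(g2 == levels(g2)[1]), n2 = sum(g2 == levels(g2)[2]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- bh_fdr(out$p)
  out <- out[, c("contrast", "F", "df1", "df2", "p", "p_fdr", "d",
                 "n1", "n2")]
  class(out) <- c("contrast_table", "data.frame")
  out
}

#' @export
print.contrast_table <- function(x, ...) {
  cat("Planned contrasts (BH-FDR across",
      nrow(x), "pairs):\n")
  df <- as.data.frame(x)
  df$F <- signif(df$F, 4); df$p <- signif(df$p, 3)
  df$p_fdr <- signif(df$p_fdr, 3); df$d <- signif(df$d, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with monotonicity enforcement; order
#' preserving. Input must lie in \[0, 1\].
#'
#' @param pvals numeric vector of raw p-values.
#' @return adjusted p-values, same order.
#' @export
bh_fdr <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` is from regressing predictor j
#' on all other predictors (with intercept). Errors on perfectly collinear
#' predictors, naming the column.
#'
#' @param design data.frame or matrix of >= 2 numeric predictors (factors
#'   are expanded to indicator columns), none constant.
#' @return named numeric vector of VIFs.
#' @export
vif <- function(design) {
  X <- stats::model.matrix(~ ., data = as.data.frame(design))[, -1,
                                                              drop = FALSE]
  if (ncol(X) < 2) stop("need >= 2 predictors")
  if (any(apply(X, 2, stats::sd) == 0)) {
    stop("constant predictor: ",
         colnames(X)[which(apply(X, 2, stats::sd) == 0)[1]])
  }
  out <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 > 1 - 1e-10) {
      stop("perfectly collinear predictor: ", colnames(X)[j])
    }
    1 / (1 - r2)
  }, 1.0)
  names(out) <- colnames(X)
  out
}

#' Regressions of outcomes on ALPS with nested covariate sets
#'
#' For each outcome and covariate set, fits
#' `outcome ~ alps [+ covariates]`, reports the ALPS coefficient, its
#' p-value (BH-adjusted across the outcome family within each covariate
#' set) and the model R^2. Intended for the combined patient groups.
#'
#' @param cohort data.frame.
#' @param outcomes character vector of outcome column names.
#' @param covariate_sets named list of character vectors of covariate
#'   column names; default `none`, `age`, `age+sex+complexity`.
#' @param alps_col name of the ALPS column (default `"alps"`).
#' @param min_n outcomes with fewer complete cases are flagged and excluded
#'   from the FDR family (default 10).
#' @return data.frame of class `regression_table`: outcome, covariate_set,
#'   beta_alps, p, p_fdr, r_squared, n, flagged.
#' @export
alps_regressions <- function(cohort, outcomes,
                             covariate_sets = list(
                               none = character(),
                               age = "age",
                               `age+sex+complexity` =
                                 c("age", "sex", "complexity")),
                             alps_col = "alps", min_n = 10) {
  rows <- list()
  for (set_name in names(covariate_sets)) {
    covs <- covariate_sets[[set_name]]
    fam <- list()
    for (oc in outcomes) {
      d <- cohort[, c(oc, alps_col, covs), drop = FALSE]
      cc <- sum(stats::complete.cases(d))
      if (cc < min_n) {
        fam[[oc]] <- data.frame(outcome = oc, covariate_set = set_name,
                                beta_alps = NA, p = NA, r_squared = NA,
                                n = cc, flagged = TRUE)
        next
      }
      design <- d[, c(alps_col, covs), drop = FALSE]
      fit <- fit_glm(d[[oc]], design)
      sm <- summary(fit$lm)$coefficients
      arow <- grep(alps_col, rownames(sm))[1]
      fam[[oc]] <- data.frame(outcome = oc, covariate_set = set_name,
                              beta_alps = sm[arow, 1], p = sm[arow, 4],
                              r_squared = fit$r_squared, n = fit$n,
                              flagged = FALSE)
    }
    fam <- do.call(rbind, fam)
    fam$p_fdr <- NA_real_
    ok <- !fam$flagged
    if (any(ok)) fam$p_fdr[ok] <- bh_fdr(fam$p[ok])
    rows[[set_name]] <- fam
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[, c("outcome", "covariate_set", "beta_alps", "p", "p_fdr",
                 "r_squared", "n", "flagged")]
  class(out) <- c("regression_table", "data.frame")
  out
}

#' Paired hemisphere comparison
#'
#' Paired t-test of the left versus right per-subject index values.
#'
#' @param alps_left,alps_right numeric vectors, equal length >= 2.
#' @return list with `t`, `df`, `p`, `mean_diff`.
#' @export
hemisphere_comparison <- function(alps_left, alps_right) {
  if (length(alps_left) != length(alps_right) || length(alps_left) < 2) {
    stop("need paired vectors of equal length >= 2")
  }
  d <- alps_left - alps_right
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(list(t = 0, df = length(d) - 1, p = 1, mean_diff = 0))
    }
    stop("constant non-zero paired differences; t statistic is infinite")
  }
  tt <- stats::t.test(alps_left, alps_right, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate))
}

#' Nonparametric group comparisons with Dunn post hoc
#'
#' Two groups: Wilcoxon rank-sum (W). More groups: Kruskal-Wallis with tie
#' correction plus Dunn pairwise z tests, BH-adjusted.
#'
#' @param values numeric vector.
#' @param groups factor.
#' @return list with `statistic` (named `W` or `chi_squared`), `p`, and for
#'   > 2 groups a `dunn` data.frame (comparison, z, p, p_fdr).
#' @export
nonparametric_tests <- function(values, groups) {
  groups <- droplevels(factor(groups))
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- droplevels(groups[keep])
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (stats::sd(values) == 0) stop("all values tied")
  if (nlevels(groups) == 2) {
    wt <- stats::wilcox.test(values ~ groups, exact = FALSE, correct = FALSE)
    return(list(statistic = c(W = unname(wt$statistic)), p = wt$p.value))
  }
  kw <- stats::kruskal.test(values, groups)
  list(statistic = c(chi_squared = unname(kw$statistic)),
       df = unname(kw$parameter), p = kw$p.value,
       dunn = dunn_posthoc(values, groups))
}

# Dunn (1964) pairwise z tests on the joint ranks with tie correction
dunn_posthoc <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    se <- sqrt((N * (N + 1) / 12 - tie_term) *
                 (1 / n[[pr[1]]] + 1 / n[[pr[2]]]))
    z <- (rbar[[pr[1]]] - rbar[[pr[2]]]) / se
    data.frame(comparison = paste(pr, collapse = " vs "), z = z,
               p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- bh_fdr(out$p)
  rownames(out) <- NULL
  out
}
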