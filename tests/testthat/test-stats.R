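test_that("the GLM engine matches the normal equations and edge cases", {
  d <- toy_ancova_data()
  # exact linear response: zero residual, R^2 = 1
  y_exact <- 2 + 3 * d$x
  fit <- fit_glm(y_exact, d["x"])
  expect_equal(fit$rss, 0, tolerance = 1e-20)
  expect_equal(fit$r_squared, 1)
  # intercept-only model: R^2 = 0
  fit0 <- fit_glm(d$y, NULL)
  expect_equal(fit0$r_squared, 0)
  expect_equal(unname(fit0$coef), mean(d$y))
  # 6-point dataset against an independent normal-equations solve
  y6 <- c(1.1, 2.0, 2.9, 4.2, 4.8, 6.1)
  x6 <- data.frame(a = c(1, 2, 3, 4, 5, 6), b = c(0, 1, 0, 1, 0, 1))
  fit6 <- fit_glm(y6, x6)
  oracle <- solve_normal_equations(cbind(1, x6$a, x6$b), y6)
  expect_equal(unname(fit6$coef), unname(oracle), tolerance = 1e-10)
  # aliased columns are named
  x_bad <- data.frame(a = 1:6, b = 2 * (1:6))
  expect_error(fit_glm(y6, x_bad), "aliased.*b")
})

test_that("omnibus ANCOVA matches hand-computed sums of squares", {
  d <- toy_ancova_data()
  # zero-noise equal means: F = 0
  f0 <- ancova_omnibus(rep(2, 12), d$g)
  expect_equal(f0$F, 0)
  # hand computation, full (group + x) vs reduced (x)
  Xf <- cbind(1, d$g == "b", d$g == "c", d$x)
  Xr <- cbind(1, d$x)
  rss <- function(X, y) {
    b <- solve_normal_equations(X, y); sum((y - X %*% b)^2)
  }
  rss_f <- rss(Xf, d$y); rss_r <- rss(Xr, d$y)
  F_hand <- ((rss_r - rss_f) / 2) / (rss_f / (12 - 4))
  fit <- ancova_omnibus(d$y, d$g, d["x"])
  expect_equal(fit$F, F_hand, tolerance = 1e-10)
  expect_equal(fit$df1, 2)
  expect_equal(fit$df2, 8)
  expect_equal(fit$p, pf(F_hand, 2, 8, lower.tail = FALSE))
  # covariate-free balanced case equals classical one-way ANOVA
  fit2 <- ancova_omnibus(d$y, d$g)
  classical <- summary(aov(y ~ g, data = d))[[1]]$`F value`[1]
  expect_equal(fit2$F, classical, tolerance = 1e-10)
})

test_that("omnibus errors when a group loses its complete cases", {
  d <- toy_ancova_data()
  x <- d$x
  x[d$g == "a"] <- NA
  expect_error(ancova_omnibus(d$y, d$g, data.frame(x = x)),
               "fewer than 2 complete cases")
})

test_that("planned contrasts recover hand-computed effect sizes", {
  # identical groups: F ~ 0, d ~ 0
  y <- rep(c(1, 2, 3, 4), 2)
  g <- factor(rep(c("a", "b"), each = 4))
  ct0 <- planned_contrasts(y, g, pairs = list(c("a", "b")))
  expect_equal(ct0$F, 0, tolerance = 1e-20)
  expect_equal(ct0$d, 0, tolerance = 1e-10)
  # means 0 and 2, pooled SD exactly 1: d = 2 (hand formula)
  y2 <- c(-1, 0, 1, 1, 2, 3)
  g2 <- factor(rep(c("b", "a"), each = 3))
  sp <- sqrt((2 * var(y2[1:3]) + 2 * var(y2[4:6])) / 4)
  d_hand <- (mean(y2[4:6]) - mean(y2[1:3])) / sp
  ct <- planned_contrasts(y2, g2, pairs = list(c("a", "b")))
  expect_equal(ct$d, d_hand, tolerance = 1e-10)
  expect_equal(ct$d, 2, tolerance = 1e-10)
  expect_error(planned_contrasts(y2, g2,
                                 pairs = list(c("a", "b"), c("b", "a"))),
               "duplicate")
})

test_that("contrast d is covariate-adjusted", {
  set.seed(7)
  n <- 200
  age <- rnorm(n, 70, 7)
  g <- factor(rep(c("a", "b"), each = n / 2))
  # group difference entirely explained by a 0.05/year age effect
  y <- 0.05 * age + rnorm(n, 0, 0.3) + ifelse(g == "a", 0.5, 0)
  ct_raw <- planned_contrasts(y, g, d_method = "raw")
  ct_adj <- planned_contrasts(y, g, covariates = data.frame(age = age))
  expect_equal(ct_adj$d, 0.5 / 0.3, tolerance = 0.25)
  expect_equal(ct_raw$contrast, ct_adj$contrast)
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(5)
  for (i in 1:25) {
    p <- runif(sample(2:12, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, bh_stepup_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= pmin(1, p * length(p)) + 1e-15))  # <= Bonferroni
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm]), adj[perm], tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("VIF equals the auxiliary-regression definition", {
  set.seed(8)
  n <- 60
  # orthogonal predictors: VIF 1
  x1 <- rep(c(-1, 1), n / 2); x2 <- rep(c(-1, -1, 1, 1), n / 4)
  v <- vif(data.frame(x1 = x1, x2 = x2))
  expect_equal(unname(v), c(1, 1), tolerance = 1e-10)
  # near-duplicate predictor explodes
  z1 <- rnorm(n); z2 <- z1 + rnorm(n, 0, 0.01); z3 <- rnorm(n)
  v2 <- vif(data.frame(z1 = z1, z2 = z2, z3 = z3))
  expect_gt(v2[["z1"]], 10)
  # 3-predictor set against the 1/(1 - R^2_j) oracle
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  X$b <- X$b + 0.5 * X$a
  v3 <- vif(X)
  for (j in 1:3) {
    r2 <- summary(lm(X[[j]] ~ ., data = X[-j]))$r.squared
    expect_equal(unname(v3[j]), 1 / (1 - r2), tolerance = 1e-10)
  }
  expect_error(vif(data.frame(a = z1, b = 2 * z1)), "collinear")
  expect_error(vif(data.frame(a = z1, b = rep(1, n))), "constant")
})

test_that("VIF agrees with the car package on a mixed design", {
  skip_if_not_installed("car")
  set.seed(9)
  d <- data.frame(alps = rnorm(50), age = rnorm(50, 70, 7),
                  sex = factor(sample(c("M", "F"), 50, TRUE)),
                  complexity = rnorm(50, 0.4, 0.05))
  y <- rnorm(50)
  ours <- vif(d)
  theirs <- car::vif(lm(y ~ alps + age + sex + complexity, data = d))
  sex_col <- grep("^sex", names(ours), value = TRUE)
  expect_equal(unname(ours[c("alps", "age", sex_col, "complexity")]),
               unname(theirs[c("alps", "age", "sex", "complexity")]),
               tolerance = 1e-8)
})

test_that("hemisphere comparison follows the paired-t hand formula", {
  l <- c(1.50, 1.42, 1.61, 1.38, 1.47)
  r <- c(1.46, 1.44, 1.55, 1.38, 1.41)
  out <- hemisphere_comparison(l, r)
  d <- l - r
  expect_equal(out$t, mean(d) / (sd(d) / sqrt(5)), tolerance = 1e-12)
  expect_equal(out$df, 4)
  # identical hemispheres: t = 0
  same <- hemisphere_comparison(l, l)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # constant non-zero difference: infinite-t guard
  expect_error(hemisphere_comparison(l, l - 1), "infinite")
})

test_that("nonparametric tests match rank arithmetic and null behaviour", {
  # two identical samples: W at its null expectation n1*n2/2, p ~ 1
  a <- c(1, 3, 5, 7); b <- c(2, 4, 6, 8)
  out2 <- nonparametric_tests(c(a, b), factor(rep(c("g1", "g2"), each = 4)))
  # hand rank-sum: g1 ranks {1,3,5,7} -> W = 16 - 4*5/2 = 6, near null E = 8
  expect_equal(unname(out2$statistic), 6)
  expect_gt(out2$p, 0.5)
  # 3-group toy: H from the hand rank formula (no ties)
  vals <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  grp <- factor(rep(c("a", "b", "c"), each = 3))
  out3 <- nonparametric_tests(vals, grp)
  rk <- rank(vals); N <- 9
  H_hand <- 12 / (N * (N + 1)) *
    sum(tapply(rk, grp, sum)^2 / tapply(rk, grp, length)) - 3 * (N + 1)
  expect_equal(unname(out3$statistic), H_hand, tolerance = 1e-10)
  # Dunn post hoc on identical group distributions: all adjusted p near 1
  set.seed(10)
  vals2 <- rep(c(2, 4, 6, 8, 10), 3)
  grp2 <- factor(rep(c("a", "b", "c"), each = 5))
  out4 <- nonparametric_tests(vals2, grp2)
  expect_true(all(out4$dunn$p_fdr > 0.9))
  expect_error(nonparametric_tests(rep(1, 9), grp), "tied")
})

test_that("ALPS regressions report coefficients, R2 and family-wise FDR", {
  set.seed(12)
  n <- 80
  co <- data.frame(alps = rnorm(n, 1.4, 0.15), age = rnorm(n, 70, 7),
                   sex = factor(sample(c("M", "F"), n, TRUE)),
                   complexity = rnorm(n, 0.4, 0.05))
  co$moca <- 10 * co$alps                      # exact linear function
  co$noise1 <- rnorm(n)
  tab <- alps_regressions(co, c("moca", "noise1"))
  r_moca <- tab[tab$outcome == "moca" & tab$covariate_set == "none", ]
  expect_equal(r_moca$r_squared, 1, tolerance = 1e-10)
  expect_equal(r_moca$beta_alps, 10, tolerance = 1e-8)
  expect_lt(r_moca$p_fdr, 1e-10)
  # adding covariates never increases RSS: R^2 non-decreasing per outcome
  for (oc in c("moca", "noise1")) {
    r2 <- tab$r_squared[tab$outcome == oc]
    expect_true(all(diff(r2) >= -1e-12))
  }
  # sparse outcomes are flagged and left out of the FDR family
  co$rare <- NA_real_; co$rare[1:5] <- rnorm(5)
  tab2 <- alps_regressions(co, c("moca", "rare"))
  expect_true(all(tab2$flagged[tab2$outcome == "rare"]))
  expect_true(all(is.na(tab2$p_fdr[tab2$outcome == "rare"])))
})

test_that("null regressions keep the FDR false-positive rate controlled", {
  set.seed(13)
  reps <- 300
  hits <- 0
  for (r in seq_len(reps)) {
    n <- 60
    co <- data.frame(alps = rnorm(n), age = rnorm(n))
    co$o1 <- rnorm(n); co$o2 <- rnorm(n); co$o3 <- rnorm(n)
    tab <- alps_regressions(co, c("o1", "o2", "o3"),
                            covariate_sets = list(none = character()))
    hits <- hits + any(tab$p_fdr < 0.05)
  }
  # family-wise FDR under the global null: expected rate <= 0.05
  expect_lt(hits / reps, 0.08)
})
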