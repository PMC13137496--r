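# Shared fixtures, built in code at test time.

# compact multi-shell table: enough directions for tensor + lmax-8 CSD
small_gtab <- function() {
  gradient_table(list(list(b = 50, n = 10), list(b = 1000, n = 30),
                      list(b = 2000, n = 64)))
}

# small noiseless phantom for fast pipeline checks
small_phantom_config <- function(...) {
  alps_phantom_config(
    dim = c(20L, 12L, 8L),
    roi_centres = list(SLF_L = c(3, 6, 4), SCR_L = c(8, 6, 4),
                       SCR_R = c(13, 6, 4), SLF_R = c(18, 6, 4)),
    noise = noise_model("none"),
    ...
  )
}

# printed toy ANCOVA fixture: 3 groups x 4 observations, one covariate
toy_ancova_data <- function() {
  data.frame(
    y = c(1.0, 1.4, 0.9, 1.2,
          2.1, 2.4, 1.9, 2.0,
          3.2, 2.8, 3.1, 3.3),
    g = factor(rep(c("a", "b", "c"), each = 4)),
    x = c(0.1, 0.3, 0.2, 0.4,
          0.2, 0.5, 0.1, 0.3,
          0.4, 0.2, 0.3, 0.5)
  )
}

# independent normal-equations solver used as the GLM oracle
solve_normal_equations <- function(X, y) {
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# brute-force BH step-up: literal definition, independent of p.adjust
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- prev
  }
  adj
}
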