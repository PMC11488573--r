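test_that("standardize centres and scales with recorded parameters", {
  df <- data.frame(a = c(1, 2, 3), b = c(10, 30, 20))
  out <- standardize(df, c("a", "b"))
  expect_equal(out$a, c(-1, 0, 1))
  expect_lt(abs(mean(out$b)), 1e-12)
  expect_equal(stats::sd(out$b), 1)
  again <- standardize(out, c("a", "b"))
  expect_equal(again$a, out$a, tolerance = 1e-12)   # idempotent
  pars <- attr(out, "standardization")
  expect_equal(pars$mean[pars$column == "a"], 2)
  expect_error(standardize(data.frame(z = rep(1, 5)), "z"), "zero variance")

  set.seed(4)
  df2 <- data.frame(x = rnorm(100, 5, 3))
  s2 <- standardize(df2, "x")
  expect_equal(mean(s2$x), 0, tolerance = 1e-12)
  expect_equal(stats::sd(s2$x), 1, tolerance = 1e-12)
})

test_that("cube root transform is odd, monotone and sign-preserving", {
  x <- c(-8, -1, 0, 1, 27)
  expect_equal(cube_root(x), c(-2, -1, 0, 1, 3))
  expect_equal(cube_root(-x), -cube_root(x))
  set.seed(5)
  z <- sort(rnorm(50))
  expect_true(all(diff(cube_root(z)) > 0))
})

test_that("REML fit matches nlme on an unbalanced dataset", {
  skip_if_not_installed("nlme")
  set.seed(42)
  g <- factor(rep(1:18, times = sample(4:14, 18, replace = TRUE)))
  n <- length(g)
  x1 <- rnorm(n); x2 <- as.numeric(g) / 10 + rnorm(n)
  y <- 1 + 0.5 * x1 - 0.3 * x2 +
    rnorm(18, 0, 0.4)[as.integer(g)] + rnorm(n, 0, 0.7)
  fit <- fit_lmm(y, cbind(1, x1 = x1, x2 = x2), g)
  ref <- nlme::lme(y ~ x1 + x2, random = ~ 1 | g,
                   data = data.frame(y, x1, x2, g), method = "REML")
  expect_equal(fit$coefficients$estimate, unname(nlme::fixef(ref)),
               tolerance = 1e-6)
  expect_equal(fit$coefficients$se, unname(sqrt(diag(stats::vcov(ref)))),
               tolerance = 1e-5)
  expect_equal(fit$sigma_e, ref$sigma, tolerance = 1e-5)
  expect_equal(fit$logLik_reml, as.numeric(stats::logLik(ref)),
               tolerance = 1e-6)
})

test_that("with no group variation the GLS solution collapses to OLS", {
  ## errors constructed with identical (zero) group means so the REML
  ## profile is maximized at the boundary theta = 0
  set.seed(10)
  g <- rep(1:10, each = 8)
  x <- rnorm(80)
  e <- rnorm(80)
  e <- e - ave(e, g)                      # group means exactly zero
  y <- 2 + 0.5 * x + e
  X <- cbind(`(Intercept)` = 1, x = x)
  fit <- fit_lmm(y, X, g)
  ols <- solve(crossprod(X), crossprod(X, y))
  expect_equal(fit$sigma_u, 0)
  expect_true(fit$boundary)
  expect_equal(fit$coefficients$estimate, unname(drop(ols)),
               tolerance = 1e-6)
})

test_that("balanced one-way variance components match the ANOVA moments", {
  set.seed(21)
  g <- 12; m <- 8
  grp <- rep(seq_len(g), each = m)
  y <- 5 + rep(rnorm(g, 0, 2), each = m) + rnorm(g * m, 0, 1)
  fit <- fit_lmm(y, matrix(1, g * m, 1,
                           dimnames = list(NULL, "(Intercept)")), grp)
  gm <- tapply(y, grp, mean)
  msb <- m * sum((gm - mean(y))^2) / (g - 1)
  msw <- sum((y - gm[grp])^2) / (g * (m - 1))
  expect_equal(fit$sigma_e^2, msw, tolerance = 1e-6)
  expect_equal(fit$sigma_u^2, (msb - msw) / m, tolerance = 1e-6)
})

test_that("REML optimum dominates a grid sweep over theta", {
  set.seed(33)
  grp <- rep(1:15, each = 6)
  x <- rnorm(90)
  y <- 1 + 0.3 * x + rep(rnorm(15, 0, 0.6), each = 6) + rnorm(90, 0, 1)
  X <- cbind(1, x = x)
  fit <- fit_lmm(y, X, grp)
  idx <- split(seq_along(y), grp)
  at_opt <- nfixpd:::reml_loglik(fit$theta, X, y, idx)
  for (th in c(0, 10^seq(-3, 1, length.out = 12))) {
    expect_gte(at_opt + 1e-7, nfixpd:::reml_loglik(th, X, y, idx))
  }
})

test_that("estimates are invariant to group relabeling and row order", {
  set.seed(60)
  grp <- rep(letters[1:8], each = 7)
  x <- rnorm(56)
  y <- 2 - 0.4 * x + rep(rnorm(8, 0, 0.5), each = 7) + rnorm(56, 0, 0.8)
  X <- cbind(1, x = x)
  f1 <- fit_lmm(y, X, grp)
  perm <- sample(56)
  f2 <- fit_lmm(y[perm], X[perm, ], grp[perm])
  f3 <- fit_lmm(y, X, factor(grp, levels = rev(letters[1:8])))
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-9)
  expect_equal(f1$coefficients$estimate, f3$coefficients$estimate,
               tolerance = 1e-9)
  expect_equal(f1$sigma_u, f2$sigma_u, tolerance = 1e-8)
})

test_that("rank-deficient designs are rejected with the aliased column", {
  set.seed(3)
  x <- rnorm(40)
  X <- cbind(`(Intercept)` = 1, x = x, x_dup = x)
  expect_error(fit_lmm(rnorm(40), X, rep(1:8, each = 5)), "x_dup")
})

test_that("variance inflation factors follow 1/(1 - R^2)", {
  set.seed(9)
  n <- 4000
  ortho <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  v <- vif(ortho)
  expect_true(all(abs(v - 1) < 0.1))
  x <- rnorm(n)
  dup <- cbind(a = x, b = x)
  expect_warning(v2 <- vif(dup), "collinear")
  expect_true(all(!is.finite(v2)))
  ## population correlation 0.8 -> VIF about 1/(1 - 0.64)
  z <- 0.8 * x + sqrt(1 - 0.64) * rnorm(n)
  v3 <- vif(cbind(x = x, z = z))
  expect_equal(unname(v3["x"]), 1 / (1 - 0.64), tolerance = 0.15)
  skip_if_not_installed("car")
  d <- data.frame(y = rnorm(n), x = x, z = z, w = rnorm(n))
  ref <- car::vif(stats::lm(y ~ x + z + w, data = d))
  expect_equal(unname(vif(cbind(x = x, z = z, w = d$w))), unname(ref),
               tolerance = 1e-8)
})

test_that("model table covers responses, variants and strict subsets", {
  set.seed(14)
  sim <- simulate_dataset(sim_config("paperlike", seed = 14L,
                                     n_species = 200L, n_sites = 15L,
                                     plots_per_site = 12L,
                                     fixer_fraction = 0.15,
                                     occ_fixer = 0.08))
  ec <- env_change_table(sim$env, sim$site_years)
  ct <- build_change_table(sim$pairs, sim$traits, sim$tree, ec)
  m <- fit_all_models(ct, responses = c("delta_prop_rich", "delta_pd"),
                      include_strict = TRUE, cube_root_variant = TRUE)
  expect_setequal(unique(m$variant[m$response == "delta_pd"]),
                  c("raw", "cube_root", "strict"))
  expect_equal(unique(m$variant[m$response == "delta_prop_rich"]), "raw")
  expect_setequal(unique(m$term),
                  c("(Intercept)", "cum_n", "delta_t", "delta_ai",
                    "baseline_prop_rich", "baseline_pd"))
  ## requesting variants does not change the raw fit
  m1 <- fit_all_models(ct, responses = "delta_pd")
  raw <- m[m$response == "delta_pd" & m$variant == "raw", ]
  expect_equal(raw$estimate, m1$estimate, tolerance = 1e-12)
  expect_true(all(vapply(attr(m, "vif"), max, numeric(1)) < 10))
})

test_that("guild contrasts agree across reference-level refits", {
  set.seed(25)
  sim <- simulate_dataset(sim_config("paperlike", seed = 25L,
                                     n_species = 200L, n_sites = 10L,
                                     plots_per_site = 8L,
                                     fixer_fraction = 0.12))
  g <- guild_pd_table(sim$pairs, sim$traits, sim$tree)
  cmp <- guild_pairwise(g)
  expect_setequal(cmp$comparison,
                  c("conserved - lost", "conserved - gained",
                    "gained - lost"))
  ## reparameterization identity: (c - l) - (c - g) = (g - l)
  expect_equal(cmp$value[cmp$comparison == "conserved - lost"] -
                 cmp$value[cmp$comparison == "conserved - gained"],
               cmp$value[cmp$comparison == "gained - lost"],
               tolerance = 1e-10)
})

test_that("diagnostics flag injected outliers without dropping them", {
  set.seed(71)
  grp <- rep(1:10, each = 10)
  x <- rnorm(100)
  y <- 1 + 0.2 * x + rep(rnorm(10, 0, 0.3), each = 10) + rnorm(100, 0, 0.5)
  y[7] <- y[7] + 10
  X <- cbind(`(Intercept)` = 1, x = x)
  fit <- fit_lmm(y, X, grp)
  d <- lmm_diagnostics(y, X, grp, fit, focal = "x")
  expect_true(7 %in% d$outliers$row)
  expect_equal(nrow(d$site_influence), 10)
  expect_equal(fit$n_obs, 100)   # nothing dropped
})
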