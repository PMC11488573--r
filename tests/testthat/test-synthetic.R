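test_that("tree simulation is deterministic, sized and ultrametric", {
  t1 <- simulate_tree(4, seed = 5)
  t2 <- simulate_tree(4, seed = 5)
  expect_identical(write_newick(t1), write_newick(t2))
  for (n in c(10, 57, 200)) {
    tr <- simulate_tree(n, seed = n)
    expect_equal(ape::Ntip(tr), n)
    expect_true(is_ultrametric_tree(tr, 1e-9))
    expect_equal(max(node_depths(tr)), 150, tolerance = 1e-9)
  }
  expect_error(simulate_tree(3), "at least 4")
})

test_that("fixer clades hit the target fraction and keep genus constancy", {
  set.seed(41)
  tr <- simulate_tree(400, seed = 41)
  taxa <- assign_fixer_clades(tr, 3, 0.1)
  frac <- mean(taxa$traits$is_fixer)
  expect_lte(abs(frac - 0.1), 0.02)
  ## fixer trait constant within genus (validate_traits enforces, but check
  ## directly against the tree partition)
  byg <- tapply(taxa$traits$is_fixer, taxa$traits$genus,
                function(z) length(unique(z)))
  expect_true(all(byg == 1))
  ## fixers form k clades: the fixer tip set is a union of whole clades,
  ## so each fixer's closest relatives inside its genus are fixers too
  expect_setequal(taxa$tree$tip.label, taxa$traits$species)
  all_fix <- assign_fixer_clades(tr, 1, 1)
  expect_true(all(all_fix$traits$is_fixer))
})

test_that("environment generator respects trends, noise and clamping", {
  sy <- data.frame(site = "s1", baseline_year = 1970L, resurvey_year = 2010L)
  cfg0 <- sim_config("paperlike",
                     ndep_noise_sd = 0, temp_noise_sd = 0,
                     precip_noise_sd = 0, pet_noise_sd = 0,
                     temp_trend = 0, ndep_ramp = 0,
                     ndep_base_sdlog = 0, temp_base_sd = 0,
                     precip_site_sd = 0, pet_site_sd = 0)
  set.seed(1)
  env <- simulate_environment(cfg0, sy)
  expect_equal(length(unique(env$n_dep)), 1)   # zero noise, zero trend
  expect_equal(length(unique(env$temp)), 1)
  set.seed(1)
  cfg1 <- sim_config("paperlike", ndep_noise_sd = 0, ndep_base_sdlog = 0)
  env1 <- simulate_environment(cfg1, sy)
  expect_true(all(diff(env1$n_dep[env1$year <= 2016]) > 0))  # monotone ramp
  s <- env1[env1$site == "s1", ]
  expect_true(all(abs(s$n_dep[s$year >= 2016] -
                        s$n_dep[s$year == 2016][1]) < 1e-12))
  expect_silent(validate_env_series(env1))
})

test_that("deposition growth approaches the configured tenfold increase", {
  set.seed(2)
  cfg <- sim_config("paperlike", n_sites = 40L)
  sy <- data.frame(site = sprintf("s%02d", 1:40),
                   baseline_year = 1966L, resurvey_year = 2010L)
  env <- simulate_environment(cfg, sy)
  rat <- vapply(sy$site, function(s) {
    e <- env[env$site == s, ]
    nb <- moving_mean_5yr(e$year, e$n_dep, 1966)
    nr <- moving_mean_5yr(e$year, e$n_dep, 2010)
    (nr - nb) / nb
  }, numeric(1))
  ## configured exponential ramp over 44 years: dN/N_base = e^(44g) - 1
  target <- exp(44 * cfg$ndep_ramp) - 1
  expect_lt(abs(mean(rat) - target) / target, 0.2)
})

test_that("survey simulation is deterministic and null-symmetric", {
  cfg <- sim_config("null", seed = 77L, n_species = 200L, n_sites = 12L,
                    plots_per_site = 8L, fixer_fraction = 0.12)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$pairs$plot, s2$pairs$plot)
  expect_identical(s1$pairs$baseline_species, s2$pairs$baseline_species)
  expect_identical(s1$env$n_dep, s2$env$n_dep)

  ## balanced loss and gain keeps the fixer proportion change centred at 0
  cfg0 <- sim_config("null", seed = 78L, n_species = 300L, n_sites = 20L,
                     plots_per_site = 15L, fixer_fraction = 0.1,
                     loss_intercept = -5, site_sd = 0,
                     gain_fixer = 0.0066, gain_nonfixer = 0.0066)
  s0 <- simulate_dataset(cfg0)
  ec <- env_change_table(s0$env, s0$site_years)
  ct <- build_change_table(s0$pairs, s0$traits, s0$tree, ec,
                           compute_pd = FALSE)
  expect_lt(abs(mean(ct$delta_prop_rich)),
            3 * stats::sd(ct$delta_prop_rich) / sqrt(nrow(ct)) + 0.005)
})

test_that("signal configuration yields a negative fitted deposition slope", {
  cfg <- sim_config("strong-signal", seed = 90L, n_species = 300L,
                    n_sites = 40L, plots_per_site = 15L,
                    fixer_fraction = 0.1)
  sim <- simulate_dataset(cfg)
  ec <- env_change_table(sim$env, sim$site_years)
  ct <- build_change_table(sim$pairs, sim$traits, sim$tree, ec,
                           compute_pd = FALSE)
  m <- fit_all_models(ct, responses = "delta_prop_rich")
  est <- m$estimate[m$term == "cum_n"]
  expect_lt(est, 0)
  expect_lt(m$p[m$term == "cum_n"], 0.05)
})

test_that("generated site years respect the configured ranges", {
  sim <- simulate_dataset(sim_config("paperlike", seed = 6L,
                                     n_species = 120L, n_sites = 30L,
                                     plots_per_site = 2L,
                                     fixer_fraction = 0.15))
  sy <- sim$site_years
  expect_true(all(sy$baseline_year >= 1955 & sy$baseline_year <= 1990))
  expect_true(all(sy$resurvey_year >= 1995 & sy$resurvey_year <= 2019))
  expect_true(all(sy$resurvey_year - sy$baseline_year >= 5))
  expect_error(sim_config("paperlike", nonsense_key = 1), "unknown config")
})
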