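## Synthetic study systems with known ground truth: a dated Yule
## phylogeny, a clade-conserved N-fixer trait, site-level environmental
## trajectories, and paired occupancy surveys in which species loss is
## driven by cumulative N deposition through a logistic model with site
## random effects. Every generator is deterministic under a fixed seed.

#' Simulate an ultrametric Yule phylogeny
#'
#' Pure-birth tree rescaled to a stated crown depth.
#'
#' @param n_species number of tips (at least 4).
#' @param seed optional integer seed (set before drawing).
#' @param crown_depth crown age the tree is rescaled to (My).
#' @return a `phylo` object with tips `t1...tn`.
#' @export
simulate_tree <- function(n_species, seed = NULL, crown_depth = 150) {
  if (n_species < 4L) stop("need at least 4 species")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_species, birth = 1, death = 0)
  depth <- max(node_depths(tree))
  tree$edge.length <- tree$edge.length * (crown_depth / depth)
  validate_phylogeny(tree)
}

## Tips descending from each internal node, as a list indexed by node id.
clade_tip_sets <- function(tree) {
  tree <- stats::reorder(tree, "cladewise")
  n <- ape::Ntip(tree)
  sets <- vector("list", max(tree$edge))
  for (i in seq_len(n)) sets[[i]] <- i
  ## edges in ape's cladewise order: process children before parents by
  ## walking the edge matrix backwards
  for (e in rev(seq_len(nrow(tree$edge)))) {
    par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    sets[[par]] <- c(sets[[par]], sets[[ch]])
  }
  sets
}

## Partition tips into clades cut at a given depth from the root: each tip
## belongs to the clade rooted at the first node on its root path whose
## depth >= cut.
depth_cut_partition <- function(tree, cut) {
  depths <- node_depths(tree)
  vapply(seq_len(ape::Ntip(tree)), function(tip) {
    path <- rev(root_path_nodes(tree, tip))   # root ... tip
    path[which(depths[path] >= cut)[1]]
  }, numeric(1))
}

#' Assign a clade-conserved N-fixer trait and taxonomy
#'
#' Chooses `k_clades` disjoint clades whose tips jointly make up the
#' target fixer fraction (within 20 percent), marks their species as
#' N-fixers, and derives genus and family labels from depth cuts of the
#' tree so that the fixer trait is constant within every genus (genera
#' that would straddle a fixer-clade boundary are split). Tips are renamed
#' to `<Genus>_s<i>` binomials.
#'
#' @param tree ultrametric `phylo` object.
#' @param k_clades number of independent fixer clades.
#' @param target_fraction target fraction of fixer tips in `(0, 1]`.
#' @param genus_cut,family_cut depths (My from the root) at which the
#'   genus and family partitions are cut; the genus cut must be deeper.
#' @return list with `tree` (tips renamed) and `traits` (data frame
#'   `species, genus, family, is_fixer`).
#' @export
assign_fixer_clades <- function(tree, k_clades, target_fraction,
                                genus_cut = 100, family_cut = 50) {
  n <- ape::Ntip(tree)
  target <- round(target_fraction * n)
  if (target < 1) stop("target fixer fraction yields no species")
  fixer_tips <- integer(0)
  if (target_fraction >= 1) {
    fixer_tips <- seq_len(n)
  } else {
    sets <- clade_tip_sets(tree)
    sizes <- lengths(sets)
    internal <- seq.int(n + 1L, max(tree$edge))
    covered <- NULL
    for (attempt in seq_len(200L)) {
      cov <- logical(n)
      ok <- TRUE
      for (k in seq_len(k_clades)) {
        remaining <- target - sum(cov)
        per <- remaining / (k_clades - k + 1L)
        cand <- internal[sizes[internal] >= max(1, floor(0.5 * per)) &
                           sizes[internal] <= max(1, ceiling(1.5 * per))]
        cand <- cand[vapply(cand, function(nd) !any(cov[sets[[nd]]]),
                            logical(1))]
        if (!length(cand)) { ok <- FALSE; break }
        nd <- cand[sample.int(length(cand), 1L)]
        cov[sets[[nd]]] <- TRUE
      }
      if (ok && abs(sum(cov) / n - target_fraction) <=
            0.2 * target_fraction) { covered <- cov; break }
    }
    if (is.null(covered))
      stop("cannot find ", k_clades,
           " disjoint clades within 20% of fixer fraction ", target_fraction)
    fixer_tips <- which(covered)
  }
  is_fixer <- seq_len(n) %in% fixer_tips

  genus_node <- depth_cut_partition(tree, genus_cut)
  family_node <- depth_cut_partition(tree, family_cut)
  ## split genera that straddle the fixer boundary so the trait is
  ## genus-constant
  gkey <- paste0(genus_node, ifelse(is_fixer, "F", "N"))
  genus <- paste0("Genus", as.integer(factor(gkey, levels = unique(gkey))))
  family <- paste0("Fam", as.integer(factor(family_node,
                                            levels = unique(family_node))))
  species <- stats::ave(genus, genus, FUN = function(g)
    paste0(g, "_s", seq_along(g)))
  tree$tip.label <- species
  traits <- data.frame(species = species, genus = genus, family = family,
                       is_fixer = as.integer(is_fixer))
  list(tree = validate_phylogeny(tree), traits = validate_traits(traits))
}

#' Simulation configuration presets
#'
#' Returns the full parameter list for a synthetic study. The
#' `"paperlike"` preset emulates a 53-site, ~1000-plot, multi-decadal
#' resurvey system with ~1500 species of which ~5 percent fix nitrogen,
#' an exponential deposition ramp reaching a roughly tenfold rate increase
#' over a typical 44-year interval, a warming trend of 0.025 degrees C per
#' year, stationary precipitation/PET, and deposition-dependent fixer loss.
#' `"null"` removes every environmental effect on loss and gain (site
#' random effects remain); `"strong-signal"` doubles the fixer-loss
#' coefficient.
#'
#' @param preset one of `"paperlike"`, `"null"`, `"strong-signal"`.
#' @param ... named overrides of individual parameters.
#' @return named list of class `nfix_sim_config`.
#' @export
sim_config <- function(preset = c("paperlike", "null", "strong-signal"),
                       ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    seed = 1L,
    n_species = 1500L,
    n_sites = 53L,
    plots_per_site = 19L,
    fixer_clades = 5L,
    fixer_fraction = 0.053,
    crown_depth = 150,
    genus_cut = 100, family_cut = 50,
    baseline_year_range = c(1955L, 1990L),
    resurvey_year_range = c(1995L, 2019L),
    interval_mean = 44, interval_sd = 15,
    ## environment
    ndep_base_meanlog = log(0.10), ndep_base_sdlog = 0.4,
    ndep_ramp = 0.055, ndep_ref_year = 1950L, ndep_noise_sd = 0.05,
    ndep_end_year = 2016L,
    temp_base_mean = 8, temp_base_sd = 2,
    temp_trend = 0.025, temp_noise_sd = 0.3,
    precip_mean = 800, precip_site_sd = 150, precip_noise_sd = 60,
    pet_mean = 700, pet_site_sd = 100, pet_noise_sd = 40,
    ## occupancy
    ## occupancy means are on the logit-normal median scale; with the
    ## species heterogeneity below the realized plot means are ~1.4x higher
    occ_fixer = 0.027, occ_nonfixer = 0.024, occ_species_sdlogit = 0.8,
    loss_intercept = -1.0,
    loss_beta_fixer = 0.030,      # per g N m^-2 cumulative deposition
    loss_beta_nonfixer = 0.006,
    site_sd = 0.5,                # SD of the site random effect (logit)
    gain_fixer = 0.004, gain_nonfixer = 0.004,
    gain_ai_fixer = 0             # optional aridity-linked fixer gains
  )
  if (preset == "null") {
    cfg$loss_beta_fixer <- 0
    cfg$loss_beta_nonfixer <- 0
    cfg$loss_intercept <- -0.62
  }
  if (preset == "strong-signal") cfg$loss_beta_fixer <- 0.06
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "nfix_sim_config")
}

#' Simulate per-site annual environmental series
#'
#' Deposition follows a site-specific exponential ramp (rates frozen at
#' `ndep_end_year`, emulating a deposition model that ends before the most
#' recent resurveys); temperature follows a linear warming trend; annual
#' precipitation and PET are stationary. All series carry lognormal or
#' Gaussian annual noise.
#'
#' @param config an `nfix_sim_config`.
#' @param site_years data frame `site, baseline_year, resurvey_year`
#'   giving the span each site's series must cover.
#' @return environmental series data frame (see [validate_env_series()]).
#' @export
simulate_environment <- function(config, site_years) {
  out <- lapply(seq_len(nrow(site_years)), function(i) {
    s <- site_years$site[i]
    years <- seq.int(site_years$baseline_year[i] - 4L,
                     site_years$resurvey_year[i])
    base_rate <- stats::rlnorm(1, config$ndep_base_meanlog,
                               config$ndep_base_sdlog)
    ramp_years <- pmin(years, config$ndep_end_year) - config$ndep_ref_year
    n_dep <- base_rate * exp(config$ndep_ramp * ramp_years) *
      exp(stats::rnorm(length(years), 0, config$ndep_noise_sd))
    t_base <- stats::rnorm(1, config$temp_base_mean, config$temp_base_sd)
    temp <- t_base + config$temp_trend * (years - min(years)) +
      stats::rnorm(length(years), 0, config$temp_noise_sd)
    p_site <- stats::rnorm(1, config$precip_mean, config$precip_site_sd)
    e_site <- stats::rnorm(1, config$pet_mean, config$pet_site_sd)
    data.frame(site = s, year = years,
               n_dep = n_dep, temp = temp,
               precip = pmax(p_site + stats::rnorm(length(years), 0,
                                                   config$precip_noise_sd), 1),
               pet = pmax(e_site + stats::rnorm(length(years), 0,
                                                config$pet_noise_sd), 1))
  })
  validate_env_series(do.call(rbind, out))
}

#' Simulate paired occupancy surveys
#'
#' Baseline presence is Bernoulli per species and plot with
#' species-specific occupancy (logit-normal around the fixer/non-fixer
#' means). Persistence to the resurvey follows
#' `logit P(lost) = a + beta_fixer * cumN * fixer + beta_nonfixer * cumN *
#' (1 - fixer) + u_site`, with `u_site ~ N(0, site_sd^2)`; gains are
#' background colonization (optionally aridity-linked for fixers).
#'
#' @param taxa output of [assign_fixer_clades()] (`tree` + `traits`).
#' @param env environmental series from [simulate_environment()].
#' @param site_years data frame `site, baseline_year, resurvey_year`.
#' @param config an `nfix_sim_config`.
#' @return survey-pair data frame (as [make_survey_pairs()]) with the
#'   per-site random effects attached as attribute `"site_effects"`.
#' @export
simulate_surveys <- function(taxa, env, site_years, config) {
  traits <- taxa$traits
  nsp <- nrow(traits)
  base_p <- stats::plogis(stats::qlogis(
    ifelse(traits$is_fixer, config$occ_fixer, config$occ_nonfixer)) +
      stats::rnorm(nsp, 0, config$occ_species_sdlogit))
  u_site <- stats::rnorm(nrow(site_years), 0, config$site_sd)
  rows <- list()
  for (i in seq_len(nrow(site_years))) {
    s <- site_years$site[i]
    ec <- env_change(env, s, site_years$baseline_year[i],
                     site_years$resurvey_year[i])
    logit_lost <- config$loss_intercept + u_site[i] +
      ifelse(traits$is_fixer,
             config$loss_beta_fixer * ec$cum_n,
             config$loss_beta_nonfixer * ec$cum_n)
    p_lost <- stats::plogis(logit_lost)
    p_gain <- ifelse(traits$is_fixer,
                     pmin(pmax(config$gain_fixer +
                                 config$gain_ai_fixer * ec$delta_ai, 0), 1),
                     config$gain_nonfixer)
    for (k in seq_len(config$plots_per_site)) {
      present0 <- stats::runif(nsp) < base_p
      lost <- present0 & (stats::runif(nsp) < p_lost)
      gained <- !present0 & (stats::runif(nsp) < p_gain)
      present1 <- (present0 & !lost) | gained
      if (!any(present0) || !any(present1)) next
      rows[[length(rows) + 1L]] <- data.frame(
        plot = paste0(s, "_p", k), site = s,
        baseline_year = site_years$baseline_year[i],
        resurvey_year = site_years$resurvey_year[i],
        baseline_species = I(list(traits$species[present0])),
        resurvey_species = I(list(traits$species[present1])))
    }
  }
  pairs <- do.call(rbind, rows)
  rownames(pairs) <- NULL
  attr(pairs, "site_effects") <- data.frame(site = site_years$site,
                                            u = u_site)
  pairs
}

#' Simulate a complete synthetic study
#'
#' Draws, in a fixed order under `config$seed`: the phylogeny, the fixer
#' clades and taxonomy, per-site survey years, the environmental series,
#' and the paired surveys.
#'
#' @param config an `nfix_sim_config` (see [sim_config()]).
#' @return list with `tree`, `traits`, `env`, `site_years`, `pairs`,
#'   `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  set.seed(config$seed)
  tree0 <- simulate_tree(config$n_species, seed = NULL,
                         crown_depth = config$crown_depth)
  taxa <- assign_fixer_clades(tree0, config$fixer_clades,
                              config$fixer_fraction,
                              genus_cut = config$genus_cut,
                              family_cut = config$family_cut)
  n_sites <- config$n_sites
  resurvey <- sample(seq.int(config$resurvey_year_range[1],
                             config$resurvey_year_range[2]),
                     n_sites, replace = TRUE)
  interval <- pmax(round(stats::rnorm(n_sites, config$interval_mean,
                                      config$interval_sd)), 20)
  baseline <- pmax(resurvey - interval, config$baseline_year_range[1])
  baseline <- pmin(baseline, config$baseline_year_range[2])
  site_years <- data.frame(site = sprintf("site%02d", seq_len(n_sites)),
                           baseline_year = as.integer(baseline),
                           resurvey_year = as.integer(resurvey))
  env <- simulate_environment(config, site_years)
  pairs <- simulate_surveys(taxa, env, site_years, config)
  list(tree = taxa$tree, traits = taxa$traits, env = env,
       site_years = site_years, pairs = pairs, config = config)
}

#' Write a synthetic dataset to disk
#'
#' Emits the four input files consumed by the readers (`community.csv`,
#' `traits.csv`, `environment.csv`, `tree.nwk`) plus a `manifest.csv`
#' recording the preset, seed and parameter values.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if absent).
#' @param force overwrite existing files.
#' @return the directory, invisibly.
#' @export
write_dataset <- function(sim, dir, force = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("community.csv", "traits.csv",
                            "environment.csv", "tree.nwk", "manifest.csv"))
  if (!force && any(file.exists(paths)))
    stop("output files exist in ", dir, "; use force = TRUE to overwrite")
  long <- do.call(rbind, lapply(seq_len(nrow(sim$pairs)), function(i) {
    rbind(data.frame(plot = sim$pairs$plot[i], site = sim$pairs$site[i],
                     survey_role = "baseline",
                     year = sim$pairs$baseline_year[i],
                     species = sim$pairs$baseline_species[[i]]),
          data.frame(plot = sim$pairs$plot[i], site = sim$pairs$site[i],
                     survey_role = "resurvey",
                     year = sim$pairs$resurvey_year[i],
                     species = sim$pairs$resurvey_species[[i]]))
  }))
  utils::write.csv(long, paths[1], row.names = FALSE)
  tr <- sim$traits
  tr$is_fixer <- as.integer(tr$is_fixer)
  utils::write.csv(tr, paths[2], row.names = FALSE)
  utils::write.csv(sim$env, paths[3], row.names = FALSE)
  write_newick(sim$tree, paths[4])
  cfg <- sim$config
  utils::write.csv(data.frame(key = names(cfg),
                              value = vapply(cfg, function(v)
                                paste(format(v), collapse = ";"),
                                character(1))),
                   paths[5], row.names = FALSE)
  invisible(dir)
}
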