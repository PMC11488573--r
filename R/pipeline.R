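## Per-plot change statistics and per-species fate statistics from paired
## vegetation surveys, a genus-level fixer trait table and a dated
## phylogeny.

#' Read a long-format community table into survey pairs
#'
#' @param file CSV with columns `plot,site,survey_role,year,species`
#'   (`survey_role` in `baseline`/`resurvey`; an optional `cover` column is
#'   ignored). Plots with multiple resurvey years keep only the most
#'   recent resurvey, mirroring standard resurvey practice.
#' @return a survey-pair data frame, see [make_survey_pairs()].
#' @export
read_community_csv <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  make_survey_pairs(df)
}

#' Assemble survey pairs from a long community table
#'
#' @param df data frame with columns `plot,site,survey_role,year,species`.
#' @return data frame with one row per plot: `plot, site, baseline_year,
#'   resurvey_year` and list-columns `baseline_species`,
#'   `resurvey_species`.
#' @export
make_survey_pairs <- function(df) {
  need <- c("plot", "site", "survey_role", "year", "species")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("community table missing columns: ",
                         paste(miss, collapse = ", "))
  if (!all(df$survey_role %in% c("baseline", "resurvey")))
    stop("survey_role must be 'baseline' or 'resurvey'")
  df$species <- normalize_species(df$species)
  plots <- unique(df$plot)
  rows <- lapply(plots, function(p) {
    d <- df[df$plot == p, , drop = FALSE]
    base <- d[d$survey_role == "baseline", , drop = FALSE]
    res <- d[d$survey_role == "resurvey", , drop = FALSE]
    if (!nrow(base) || !nrow(res))
      stop("plot ", p, " lacks a baseline or resurvey")
    if (length(unique(base$year)) > 1L)
      stop("plot ", p, " has multiple baseline years")
    res <- res[res$year == max(res$year), , drop = FALSE]  # most recent only
    by <- base$year[1]; ry <- res$year[1]
    if (by >= ry) stop("plot ", p, ": baseline year must precede resurvey year")
    data.frame(plot = p, site = d$site[1], baseline_year = by,
               resurvey_year = ry,
               baseline_species = I(list(unique(base$species))),
               resurvey_species = I(list(unique(res$species))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

fixer_set <- function(species, traits) {
  unknown <- setdiff(species, traits$species)
  if (length(unknown))
    stop("species missing from trait table: ", paste(unknown, collapse = ", "))
  species[traits$is_fixer[match(species, traits$species)]]
}

#' Classify a plot's N-fixers into lost/gained/conserved guilds
#'
#' Lost = fixers present at baseline but absent at resurvey; gained =
#' present at resurvey only; conserved = present in both.
#'
#' @param baseline_species,resurvey_species character vectors of species
#'   present in each survey.
#' @param traits validated trait table.
#' @return list with character vectors `lost`, `gained`, `conserved`.
#' @export
classify_guilds <- function(baseline_species, resurvey_species, traits) {
  traits <- validate_traits(traits)
  b <- fixer_set(unique(normalize_species(baseline_species)), traits)
  r <- fixer_set(unique(normalize_species(resurvey_species)), traits)
  list(lost = setdiff(b, r), gained = setdiff(r, b),
       conserved = intersect(b, r))
}

#' Proportion of N-fixers in a species set
#'
#' Richness of fixers divided by total richness.
#'
#' @param species character vector, non-empty.
#' @param traits validated trait table.
#' @return proportion in `[0, 1]`.
#' @export
fixer_proportion <- function(species, traits) {
  species <- unique(normalize_species(species))
  if (!length(species)) stop("species set is empty")
  length(fixer_set(species, traits)) / length(species)
}

#' Change in the N-fixer share of Faith's PD between surveys
#'
#' Resurvey minus baseline value of (fixer Faith's PD) / (total Faith's
#' PD). An empty fixer set contributes PD 0.
#'
#' @param baseline_species,resurvey_species species sets of the two
#'   surveys, each non-empty.
#' @param traits validated trait table.
#' @param tree phylogeny containing all observed species.
#' @return change in PD proportion.
#' @export
delta_pd_proportion <- function(baseline_species, resurvey_species, traits,
                                tree) {
  traits <- validate_traits(traits)
  prop_one <- function(sp) {
    sp <- unique(normalize_species(sp))
    if (!length(sp)) stop("survey species set is empty")
    fx <- fixer_set(sp, traits)
    total <- faith_pd(tree, sp)
    if (total <= 0) stop("total Faith's PD is not positive")
    if (!length(fx)) 0 else faith_pd(tree, fx) / total
  }
  prop_one(resurvey_species) - prop_one(baseline_species)
}

#' Per-species fate statistics across plots
#'
#' For each N-fixer species, counts the plots where it was conserved (PC),
#' lost (PL) and gained (PG), and derives loss/gain probabilities and the
#' net plot-occupancy change `delta_p = (PG - PL) / (PC + PG + PL)`.
#'
#' @param guilds list of per-plot guild partitions as returned by
#'   [classify_guilds()].
#' @param prob_denominator `"occurrence"` (default) divides PL and PG by
#'   PC + PL + PG, the number of plots where the species occurred in at
#'   least one survey; `"baseline"` divides PL by PC + PL (plots present at
#'   baseline) and PG by PC + PG.
#' @return data frame `species, PC, PL, PG, p_lost, p_gained, delta_p`.
#' @export
species_fates <- function(guilds,
                          prob_denominator = c("occurrence", "baseline")) {
  prob_denominator <- match.arg(prob_denominator)
  if (!length(guilds)) stop("at least one plot partition is required")
  count <- function(role) {
    tab <- table(unlist(lapply(guilds, `[[`, role)))
    tab
  }
  tabs <- lapply(c(conserved = "conserved", lost = "lost", gained = "gained"),
                 count)
  species <- sort(unique(unlist(lapply(tabs, names))))
  get <- function(tab, sp) ifelse(sp %in% names(tab), as.integer(tab[sp]), 0L)
  PC <- vapply(species, function(s) get(tabs$conserved, s), integer(1))
  PL <- vapply(species, function(s) get(tabs$lost, s), integer(1))
  PG <- vapply(species, function(s) get(tabs$gained, s), integer(1))
  n_occ <- PC + PL + PG
  if (prob_denominator == "occurrence") {
    p_lost <- PL / n_occ
    p_gained <- PG / n_occ
  } else {
    p_lost <- ifelse(PC + PL > 0, PL / (PC + PL), 0)
    p_gained <- ifelse(PC + PG > 0, PG / (PC + PG), 0)
  }
  out <- data.frame(species = species, PC = PC, PL = PL, PG = PG,
                    p_lost = p_lost, p_gained = p_gained,
                    delta_p = (PG - PL) / n_occ)
  rownames(out) <- NULL
  out
}

#' Plot-filter flags for the analysis variants
#'
#' @param n_fix_base,n_fix_res fixer richness at baseline and resurvey.
#' @return data frame of logicals `keep_richness` (at least one fixer in
#'   either survey), `keep_pd` (at least two fixers in one survey),
#'   `keep_strict` (at least two fixers in both surveys).
#' @export
plot_filters <- function(n_fix_base, n_fix_res) {
  data.frame(keep_richness = n_fix_base >= 1L | n_fix_res >= 1L,
             keep_pd = n_fix_base >= 2L | n_fix_res >= 2L,
             keep_strict = n_fix_base >= 2L & n_fix_res >= 2L)
}

#' Build the per-plot change table
#'
#' Derives, for every plot passing the chosen filter, the response
#' variables (change in fixer richness proportion, change in fixer Faith's
#' PD, change in the fixer share of Faith's PD, and the MPD/MNTD variants
#' under the single-fixer 0 convention), their baseline values, and the
#' site-level environmental predictors.
#'
#' @param pairs survey-pair data frame from [make_survey_pairs()].
#' @param traits validated trait table.
#' @param tree phylogeny containing every observed species (see
#'   [prepare_phylogeny()]).
#' @param env_changes output of [env_change_table()] (or any data frame
#'   with `site, baseline_year, resurvey_year, cum_n, delta_t, delta_ai`).
#' @param filter `"richness"` keeps plots with at least one fixer in either
#'   survey; `"pd"` requires at least two fixers in one survey; `"strict"`
#'   requires at least two in both.
#' @param drop_low_resolution drop genus-level identifications (species
#'   names whose epithet is `sp`/`sp.`) before computing anything; the
#'   default keeps them.
#' @param compute_pd set to `FALSE` to skip the phylogenetic responses
#'   (their columns are filled with `NA`), for richness-only replicate
#'   studies where the tree is not needed.
#' @return data frame with one row per retained plot; includes the filter
#'   flags so variant subsets can be taken without recomputation.
#' @export
build_change_table <- function(pairs, traits, tree, env_changes,
                               filter = c("richness", "pd", "strict"),
                               drop_low_resolution = FALSE,
                               compute_pd = TRUE) {
  filter <- match.arg(filter)
  traits <- validate_traits(traits)
  missing_env <- setdiff(unique(pairs$site), unique(env_changes$site))
  if (length(missing_env))
    stop("missing environmental rows for sites: ",
         paste(missing_env, collapse = ", "))
  strip_lowres <- function(sp) sp[!grepl("_sp\\.?$", sp)]
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    b <- unique(normalize_species(pairs$baseline_species[[i]]))
    r <- unique(normalize_species(pairs$resurvey_species[[i]]))
    if (drop_low_resolution) { b <- strip_lowres(b); r <- strip_lowres(r) }
    if (!length(b) || !length(r)) return(NULL)
    fb <- fixer_set(b, traits); fr <- fixer_set(r, traits)
    flags <- plot_filters(length(fb), length(fr))
    if (!flags$keep_richness) return(NULL)
    if (compute_pd) {
      mb <- pd_metrics(tree, fb); mr <- pd_metrics(tree, fr)
      tb <- faith_pd(tree, b); tr <- faith_pd(tree, r)
    } else {
      mb <- mr <- data.frame(faith_pd = NA_real_, mpd = NA_real_,
                             mntd = NA_real_)
      tb <- tr <- NA_real_
    }
    ## single/empty-set MPD/MNTD -> 0 convention (only when PD is computed)
    z <- function(x) if (compute_pd) ifelse(is.na(x), 0, x) else x
    data.frame(
      plot = pairs$plot[i], site = pairs$site[i],
      baseline_year = pairs$baseline_year[i],
      resurvey_year = pairs$resurvey_year[i],
      n_fix_base = length(fb), n_fix_res = length(fr),
      baseline_prop_rich = length(fb) / length(b),
      delta_prop_rich = length(fr) / length(r) - length(fb) / length(b),
      baseline_pd = mb$faith_pd,
      delta_pd = mr$faith_pd - mb$faith_pd,
      baseline_prop_pd = mb$faith_pd / tb,
      delta_prop_pd = mr$faith_pd / tr - mb$faith_pd / tb,
      baseline_mpd = z(mb$mpd), delta_mpd = z(mr$mpd) - z(mb$mpd),
      baseline_mntd = z(mb$mntd), delta_mntd = z(mr$mntd) - z(mb$mntd),
      flags)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || !nrow(tab))
    stop("no plots contain an N-fixer in either survey")
  key <- c("site", "baseline_year", "resurvey_year")
  idx <- match(interaction(tab[key], drop = TRUE),
               interaction(env_changes[key], drop = TRUE))
  if (anyNA(idx))
    stop("missing environmental rows for site/year combinations of sites: ",
         paste(unique(tab$site[is.na(idx)]), collapse = ", "))
  tab$cum_n <- env_changes$cum_n[idx]
  tab$delta_t <- env_changes$delta_t[idx]
  tab$delta_ai <- env_changes$delta_ai[idx]
  keep <- switch(filter, richness = tab$keep_richness, pd = tab$keep_pd,
                 strict = tab$keep_strict)
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-plot, per-guild phylogenetic diversity table
#'
#' One row per (plot, non-empty guild) with Faith's PD, MPD and MNTD under
#' the single-species MPD/MNTD = 0 convention.
#'
#' @param pairs survey-pair data frame.
#' @param traits validated trait table.
#' @param tree phylogeny containing every observed species.
#' @return data frame `plot, site, guild, n_species, faith_pd, mpd, mntd`.
#' @export
guild_pd_table <- function(pairs, traits, tree) {
  traits <- validate_traits(traits)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    g <- classify_guilds(pairs$baseline_species[[i]],
                         pairs$resurvey_species[[i]], traits)
    out <- lapply(names(g), function(guild) {
      sp <- g[[guild]]
      if (!length(sp)) return(NULL)
      cbind(data.frame(plot = pairs$plot[i], site = pairs$site[i],
                       guild = guild), pd_metrics(tree, sp))
    })
    do.call(rbind, out)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) stop("no plot has any N-fixer guild")
  rownames(tab) <- NULL
  names(tab)[names(tab) == "n_taxa"] <- "n_species"
  tab
}

#' Guild partitions for every plot
#'
#' @param pairs survey-pair data frame.
#' @param traits validated trait table.
#' @return named list (by plot id) of [classify_guilds()] partitions.
#' @export
all_guild_partitions <- function(pairs, traits) {
  traits <- validate_traits(traits)
  out <- lapply(seq_len(nrow(pairs)), function(i)
    classify_guilds(pairs$baseline_species[[i]],
                    pairs$resurvey_species[[i]], traits))
  names(out) <- pairs$plot
  out
}
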