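## Environmental change predictors from per-site annual series:
## cumulative N deposition, 5-year moving-mean temperature change and
## UNEP aridity-index change.

#' UNEP aridity index
#'
#' AI = P / PET, annual precipitation over potential evapotranspiration.
#' Higher values indicate lower aridity.
#'
#' @param precip annual precipitation (mm), `>= 0`.
#' @param pet potential evapotranspiration (mm), `> 0`.
#' @return dimensionless aridity index, vectorized.
#' @export
aridity_index <- function(precip, pet) {
  if (any(!is.finite(pet)) || any(pet <= 0)) stop("PET must be positive")
  if (any(precip < 0)) stop("precipitation must be non-negative")
  precip / pet
}

#' Read a per-site annual environmental series
#'
#' @param file CSV with columns `site,year,n_dep,temp,precip,pet`; units
#'   g N m^-2 yr^-1, degrees C, mm, mm.
#' @return validated data frame ordered by site and year.
#' @export
read_env_csv <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  validate_env_series(df)
}

#' Validate an environmental series table
#'
#' Enforces consecutive years within each site, non-negative deposition and
#' precipitation, and positive PET.
#'
#' @param df data frame with columns `site,year,n_dep,temp,precip,pet`.
#' @return the validated data frame, ordered by site then year.
#' @export
validate_env_series <- function(df) {
  need <- c("site", "year", "n_dep", "temp", "precip", "pet")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("environmental table missing columns: ",
                         paste(miss, collapse = ", "))
  df <- df[order(df$site, df$year), , drop = FALSE]
  for (s in unique(df$site)) {
    yrs <- df$year[df$site == s]
    if (any(diff(yrs) != 1L))
      stop("years are not consecutive for site ", s)
  }
  if (any(df$n_dep < 0)) stop("n_dep must be non-negative")
  if (any(df$precip < 0)) stop("precip must be non-negative")
  if (any(df$pet <= 0)) stop("pet must be positive")
  rownames(df) <- NULL
  df
}

site_series <- function(env, site) {
  s <- env[env$site == site, , drop = FALSE]
  if (!nrow(s)) stop("no environmental series for site ", site)
  s[order(s$year), , drop = FALSE]
}

#' Five-year moving mean ending at a survey year
#'
#' Arithmetic mean of the annual values for the survey year and its four
#' preceding years.
#'
#' @param years integer vector of calendar years.
#' @param values numeric vector of annual values, parallel to `years`.
#' @param survey_year year of the survey.
#' @return the 5-year mean.
#' @export
moving_mean_5yr <- function(years, values, survey_year) {
  window <- seq.int(survey_year - 4L, survey_year)
  idx <- match(window, years)
  if (anyNA(idx))
    stop("missing years in 5-year window ending ", survey_year, ": ",
         paste(window[is.na(idx)], collapse = ", "))
  mean(values[idx])
}

#' Cumulative N deposition between two surveys
#'
#' Sums the annual deposition amounts over the interval between the two
#' survey years. The default interval convention is half-open
#' `(baseline_year, resurvey_year]`: deposition accumulated after the
#' baseline survey up to and including the resurvey year, which keeps sums
#' additive over abutting intervals. For years beyond the end of the
#' series, the last available year's rate is carried forward (the
#' deposition series typically ends before the most recent resurveys).
#'
#' @param years integer vector of calendar years with deposition rates.
#' @param rates annual deposition rates (g N m^-2 yr^-1), parallel to
#'   `years`.
#' @param baseline_year,resurvey_year survey years,
#'   `baseline_year < resurvey_year`.
#' @param include_baseline_year logical; when `TRUE` the closed interval
#'   `[baseline_year, resurvey_year]` is used instead.
#' @return cumulative deposition (g N m^-2).
#' @export
cumulative_n <- function(years, rates, baseline_year, resurvey_year,
                         include_baseline_year = FALSE) {
  if (baseline_year >= resurvey_year)
    stop("baseline_year must precede resurvey_year")
  start <- if (include_baseline_year) baseline_year else baseline_year + 1L
  if (start < min(years))
    stop("interval starts (", start, ") before the deposition series (",
         min(years), ")")
  interval <- seq.int(start, resurvey_year)
  idx <- match(interval, years)
  last_rate <- rates[which.max(years)]
  vals <- ifelse(is.na(idx), last_rate, rates[idx])
  ## only years *after* the series end are clamped; gaps inside the series
  ## would be a data error caught by the reader
  if (any(is.na(idx) & interval < max(years)))
    stop("deposition series has internal gaps in ",
         paste(interval[is.na(idx) & interval < max(years)], collapse = ", "))
  sum(vals)
}

#' Environmental change predictors for one site and survey pair
#'
#' Computes the three predictors entering the mixed models: cumulative N
#' deposition over the between-survey interval (with end-of-series clamp),
#' the difference in 5-year moving-mean temperature, and the difference in
#' 5-year moving-mean UNEP aridity index (AI computed per year, then
#' averaged).
#'
#' @param env validated environmental series table.
#' @param site site id.
#' @param baseline_year,resurvey_year survey years.
#' @param include_baseline_year passed to [cumulative_n()].
#' @return one-row data frame `site, cum_n, delta_t, delta_ai`.
#' @export
env_change <- function(env, site, baseline_year, resurvey_year,
                       include_baseline_year = FALSE) {
  s <- site_series(env, site)
  ai <- aridity_index(s$precip, s$pet)
  data.frame(
    site = site,
    cum_n = cumulative_n(s$year, s$n_dep, baseline_year, resurvey_year,
                         include_baseline_year),
    delta_t = moving_mean_5yr(s$year, s$temp, resurvey_year) -
      moving_mean_5yr(s$year, s$temp, baseline_year),
    delta_ai = moving_mean_5yr(s$year, ai, resurvey_year) -
      moving_mean_5yr(s$year, ai, baseline_year)
  )
}

#' Environmental change for every site/survey-pair combination
#'
#' @param env validated environmental series table.
#' @param pairs data frame with columns `site, baseline_year,
#'   resurvey_year` (one row per site or per plot; duplicated site rows are
#'   collapsed to unique combinations).
#' @param include_baseline_year passed to [cumulative_n()].
#' @return data frame `site, baseline_year, resurvey_year, cum_n, delta_t,
#'   delta_ai` with one row per unique combination.
#' @export
env_change_table <- function(env, pairs, include_baseline_year = FALSE) {
  env <- validate_env_series(env)
  key <- unique(pairs[, c("site", "baseline_year", "resurvey_year")])
  missing_sites <- setdiff(unique(key$site), unique(env$site))
  if (length(missing_sites))
    stop("no environmental series for sites: ",
         paste(missing_sites, collapse = ", "))
  out <- do.call(rbind, lapply(seq_len(nrow(key)), function(i) {
    ec <- env_change(env, key$site[i], key$baseline_year[i],
                     key$resurvey_year[i], include_baseline_year)
    cbind(key[i, , drop = FALSE], ec[, c("cum_n", "delta_t", "delta_ai")])
  }))
  rownames(out) <- NULL
  out
}
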