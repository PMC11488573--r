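## Random-intercept linear mixed models by profiled restricted maximum
## likelihood. For a single grouping factor the marginal covariance is
## block diagonal, V_i = sigma_e^2 (I + theta J) with theta =
## sigma_u^2 / sigma_e^2, so V^-1 and log|V| have closed forms and the
## whole fit reduces to a bounded one-dimensional optimization in theta
## with an analytic GLS inner solve.

#' Standardize columns to mean 0, SD 1
#'
#' @param df data frame.
#' @param columns character vector of numeric column names.
#' @return `df` with the named columns centred and scaled (sample SD);
#'   the original means and SDs are attached as attribute
#'   `"standardization"` for back-transforming coefficients.
#' @export
standardize <- function(df, columns) {
  miss <- setdiff(columns, names(df))
  if (length(miss)) stop("columns not found: ", paste(miss, collapse = ", "))
  params <- data.frame(column = columns, mean = NA_real_, sd = NA_real_)
  for (i in seq_along(columns)) {
    x <- df[[columns[i]]]
    if (!is.numeric(x)) stop("column ", columns[i], " is not numeric")
    m <- mean(x); s <- stats::sd(x)
    if (!is.finite(s) || s == 0)
      stop("column ", columns[i], " has zero variance; cannot standardize")
    df[[columns[i]]] <- (x - m) / s
    params$mean[i] <- m; params$sd[i] <- s
  }
  attr(df, "standardization") <- params
  df
}

#' Signed cube-root transform
#'
#' `sign(x) |x|^(1/3)`: a monotone odd transform that preserves sign and
#' maps zero to zero, suitable for responses (like PD change) that take
#' both signs.
#'
#' @param x numeric vector.
#' @return transformed vector.
#' @export
cube_root <- function(x) sign(x) * abs(x)^(1 / 3)

## Cross-products under V^-1 = blockdiag(I - c_i J), c_i = theta/(1+n_i theta),
## for the design X, response y, and group index list.
lmm_profile <- function(theta, X, y, groups_idx) {
  p <- ncol(X)
  XtVX <- matrix(0, p, p)
  XtVy <- numeric(p)
  yty <- 0
  logdetW <- 0
  for (idx in groups_idx) {
    Xi <- X[idx, , drop = FALSE]
    yi <- y[idx]
    ni <- length(idx)
    ci <- theta / (1 + ni * theta)
    sx <- colSums(Xi)
    sy <- sum(yi)
    XtVX <- XtVX + crossprod(Xi) - ci * tcrossprod(sx)
    XtVy <- XtVy + crossprod(Xi, yi) - ci * sx * sy
    yty <- yty + sum(yi^2) - ci * sy^2
    logdetW <- logdetW + log1p(ni * theta)
  }
  R <- chol(XtVX)
  beta <- backsolve(R, backsolve(R, XtVy, transpose = TRUE))
  rss <- max(yty - sum(XtVy * beta), 0)
  list(beta = beta, rss = rss, XtVX = XtVX,
       logdetW = logdetW, logdetXtVX = 2 * sum(log(diag(R))))
}

reml_loglik <- function(theta, X, y, groups_idx) {
  n <- length(y); p <- ncol(X)
  pr <- lmm_profile(theta, X, y, groups_idx)
  s2 <- pr$rss / (n - p)
  -0.5 * ((n - p) * (log(2 * pi * s2) + 1) + pr$logdetW + pr$logdetXtVX)
}

ml_loglik <- function(theta, X, y, groups_idx) {
  n <- length(y)
  pr <- lmm_profile(theta, X, y, groups_idx)
  s2 <- pr$rss / n
  -0.5 * (n * (log(2 * pi * s2) + 1) + pr$logdetW)
}

## Method-of-moments start for theta from one-way residual variation.
theta_mom <- function(X, y, groups_idx) {
  res <- stats::lm.fit(X, y)$residuals
  gm <- vapply(groups_idx, function(i) mean(res[i]), numeric(1))
  nbar <- mean(lengths(groups_idx))
  msw <- sum(vapply(groups_idx, function(i)
    sum((res[i] - mean(res[i]))^2), numeric(1))) /
    max(length(res) - length(groups_idx), 1L)
  msb <- stats::var(gm) * nbar
  max((msb - msw) / (nbar * msw), 0)
}

#' Fit a random-intercept linear mixed model
#'
#' REML estimation of the site (group) intercept variance via a profiled
#' one-dimensional likelihood in `theta = sigma_u^2/sigma_e^2`, with GLS
#' fixed effects at the optimum. Deterministic: the optimizer is a bounded
#' golden-section/parabolic search (relative tolerance 1e-8) started from
#' a method-of-moments value. Fixed-effect t-tests use containment-style
#' degrees of freedom `n_obs - n_groups - (p - 1)` where p counts fixed
#' effects including the intercept.
#'
#' @param y numeric response.
#' @param X design matrix (including the intercept column).
#' @param groups grouping factor (random intercept), at least two levels.
#' @param theta optional fixed value of the variance ratio
#'   `sigma_u^2/sigma_e^2`; when supplied the optimization is skipped and
#'   GLS is computed at that value (used for reference-level refits that
#'   must share one covariance estimate exactly).
#' @return object of class `nfix_lmm`: list with `coefficients` (data
#'   frame term/estimate/se/t/df/p), `sigma_u`, `sigma_e`, `theta`,
#'   `logLik_reml`, `logLik_ml`, `n_obs`, `n_groups`, `converged`,
#'   `boundary`.
#' @export
fit_lmm <- function(y, X, groups, theta = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  groups <- factor(groups)
  if (length(y) != nrow(X) || length(groups) != length(y))
    stop("y, X and groups must have matching lengths")
  if (anyNA(y) || anyNA(X)) stop("missing values in y or X")
  if (nlevels(groups) < 2L) stop("need at least two groups")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    stop("design is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  groups_idx <- split(seq_along(y), groups)
  n <- length(y); p <- ncol(X); g <- nlevels(groups)

  converged <- TRUE
  if (is.null(theta)) {
    start <- theta_mom(X, y, groups_idx)
    upper <- max(100, 100 * start)
    neg <- function(th) -reml_loglik(th, X, y, groups_idx)
    opt <- stats::optimize(neg, interval = c(0, upper), tol = 1e-8)
    theta <- opt$minimum
    ## endpoint check: the boundary theta = 0 is a genuine candidate
    if (neg(0) <= opt$objective) theta <- 0
    ## guard against an optimum pinned at the search ceiling
    if (theta > 0.99 * upper) {
      opt2 <- stats::optimize(neg, interval = c(0, upper * 100), tol = 1e-8)
      theta <- opt2$minimum
      converged <- theta < 0.99 * upper * 100
    }
  } else {
    stopifnot(is.numeric(theta), length(theta) == 1L, theta >= 0)
  }

  pr <- lmm_profile(theta, X, y, groups_idx)
  s2 <- pr$rss / (n - p)
  se <- sqrt(diag(chol2inv(chol(pr$XtVX))) * s2)
  df <- n - g - (p - 1L)
  tval <- drop(pr$beta) / se
  coefs <- data.frame(
    term = colnames(X) %||% paste0("b", seq_len(p)),
    estimate = drop(pr$beta), se = se, t = tval, df = df,
    p = 2 * stats::pt(-abs(tval), df))
  rownames(coefs) <- NULL
  structure(list(
    coefficients = coefs,
    sigma_u = sqrt(theta * s2), sigma_e = sqrt(s2), theta = theta,
    logLik_reml = reml_loglik(theta, X, y, groups_idx),
    logLik_ml = ml_loglik(theta, X, y, groups_idx),
    n_obs = n, n_groups = g, converged = converged,
    boundary = theta == 0), class = "nfix_lmm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.nfix_lmm <- function(x, ...) {
  cat("Random-intercept linear mixed model (profiled REML)\n")
  cat(sprintf("n = %d observations, %d groups; sigma_site = %.4g, sigma_resid = %.4g\n",
              x$n_obs, x$n_groups, x$sigma_u, x$sigma_e))
  cat(sprintf("REML logLik = %.3f\n", x$logLik_reml))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing predictor j on the remaining
#' predictors (intercept included).
#'
#' @param X matrix or data frame of predictors (no intercept column), at
#'   least two.
#' @return named numeric vector of VIFs; perfectly collinear predictors
#'   return `Inf` with a warning.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("VIF needs at least two predictors")
  out <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(X)
  if (any(!is.finite(out)))
    warning("perfectly collinear predictors: ",
            paste(names(out)[!is.finite(out)], collapse = ", "))
  out
}

#' Residual and influence diagnostics for a fitted model
#'
#' Reports (never acts on) standardized marginal residuals exceeding a
#' threshold and the change in a focal slope when each site is left out.
#'
#' @param y,X,groups the data the model was fitted to.
#' @param fit an `nfix_lmm` object fitted to them.
#' @param focal name of the fixed-effect column to track under site
#'   deletion (default: second column, the first non-intercept term).
#' @param threshold flag residuals with `|z| >` this value.
#' @return list with `outliers` (data frame row/residual) and
#'   `site_influence` (data frame site/slope_change).
#' @export
lmm_diagnostics <- function(y, X, groups, fit,
                            focal = colnames(X)[2], threshold = 4) {
  X <- as.matrix(X)
  res <- y - drop(X %*% fit$coefficients$estimate)
  z <- res / sqrt(fit$sigma_u^2 + fit$sigma_e^2)
  out <- data.frame(row = which(abs(z) > threshold),
                    residual = z[abs(z) > threshold])
  jcol <- match(focal, fit$coefficients$term)
  infl <- vapply(levels(factor(groups)), function(s) {
    keep <- groups != s
    refit <- fit_lmm(y[keep], X[keep, , drop = FALSE], droplevels(factor(groups[keep])))
    refit$coefficients$estimate[jcol] - fit$coefficients$estimate[jcol]
  }, numeric(1))
  list(outliers = out,
       site_influence = data.frame(site = levels(factor(groups)),
                                   slope_change = unname(infl)))
}

#' Fit the full set of change models
#'
#' One random-intercept model per response: change in fixer richness
#' proportion (richness filter), change in fixer Faith's PD and in the
#' fixer PD share (PD filter), optionally the MPD/MNTD variants and the
#' strict (two fixers in both surveys) subset, each with standardized
#' cumulative N deposition, temperature change, aridity change and the
#' response's baseline value as fixed effects and site as the random
#' intercept. A signed cube-root variant of each PD response can be added.
#'
#' @param change_table output of [build_change_table()] under the
#'   `"richness"` filter (the variants subset it by the stored flags).
#' @param responses which responses to fit.
#' @param include_strict also fit each PD response on the strict subset.
#' @param cube_root_variant also fit each PD response cube-root
#'   transformed.
#' @param extra_predictors names of additional columns (e.g. canopy-cover
#'   change) to include, standardized, as fixed effects.
#' @return data frame with one row per (response, variant, term):
#'   `response, variant, filter, term, estimate, se, t, df, p, n_obs,
#'   n_groups, sigma_u, sigma_e`, plus the per-model VIFs as an attribute
#'   `"vif"`.
#' @export
fit_all_models <- function(change_table,
                           responses = c("delta_prop_rich", "delta_pd",
                                         "delta_prop_pd", "delta_mpd",
                                         "delta_mntd"),
                           include_strict = FALSE,
                           cube_root_variant = FALSE,
                           extra_predictors = character(0)) {
  responses <- match.arg(responses, several.ok = TRUE)
  baseline_of <- c(delta_prop_rich = "baseline_prop_rich",
                   delta_pd = "baseline_pd",
                   delta_prop_pd = "baseline_prop_pd",
                   delta_mpd = "baseline_mpd",
                   delta_mntd = "baseline_mntd")
  filter_of <- function(resp) if (resp == "delta_prop_rich") "keep_richness" else "keep_pd"
  rows <- list(); vifs <- list()
  fit_one <- function(resp, flag, label, transform) {
    dat <- change_table[change_table[[flag]], , drop = FALSE]
    preds <- c("cum_n", "delta_t", "delta_ai", baseline_of[[resp]],
               extra_predictors)
    dat <- standardize(dat, unique(preds))
    X <- as.matrix(cbind(`(Intercept)` = 1, dat[, unique(preds)]))
    yv <- dat[[resp]]
    if (transform) yv <- cube_root(yv)
    fit <- fit_lmm(yv, X, dat$site)
    vifs[[paste(resp, label, sep = ".")]] <<- vif(as.matrix(dat[, unique(preds)]))
    cbind(data.frame(response = resp, variant = label,
                     filter = sub("keep_", "", flag)),
          fit$coefficients,
          n_obs = fit$n_obs, n_groups = fit$n_groups,
          sigma_u = fit$sigma_u, sigma_e = fit$sigma_e)
  }
  for (resp in responses) {
    rows[[length(rows) + 1L]] <- fit_one(resp, filter_of(resp), "raw", FALSE)
    if (cube_root_variant && resp != "delta_prop_rich")
      rows[[length(rows) + 1L]] <- fit_one(resp, filter_of(resp), "cube_root", TRUE)
    if (include_strict && resp != "delta_prop_rich")
      rows[[length(rows) + 1L]] <- fit_one(resp, "keep_strict", "strict", FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "vif") <- vifs
  out
}

#' Pairwise guild comparisons of phylogenetic diversity
#'
#' Mixed model of a PD metric on guild (lost / gained / conserved) with a
#' site random intercept, refitted under each reference level so that all
#' three pairwise contrasts are read off as fixed-effect coefficients
#' (the construction used for guild comparison tables in resurvey
#' studies). REML is invariant to this reparameterization, so the variance
#' components are estimated once (under a canonical level ordering) and
#' every refit computes its GLS fixed effects at that shared estimate;
#' shared contrasts therefore agree across refits to machine precision.
#'
#' @param guild_table output of [guild_pd_table()].
#' @param metric which PD column to compare.
#' @return data frame `comparison, value, se, t, df, p` with rows
#'   `conserved - lost`, `conserved - gained`, `gained - lost`; the value
#'   is the first-named guild's mean minus the second's.
#' @export
guild_pairwise <- function(guild_table,
                           metric = c("faith_pd", "mpd", "mntd")) {
  metric <- match.arg(metric)
  dat <- guild_table[!is.na(guild_table[[metric]]), , drop = FALSE]
  present <- intersect(c("conserved", "gained", "lost"), unique(dat$guild))
  if (length(present) < 2L) stop("need at least two guild levels present")
  fit_ref <- function(ref, theta = NULL) {
    lev <- c(ref, setdiff(present, ref))
    f <- factor(dat$guild, levels = lev)
    X <- stats::model.matrix(~ f)
    colnames(X) <- c("(Intercept)", lev[-1])
    fit_lmm(dat[[metric]], X, dat$site, theta = theta)
  }
  canonical <- fit_ref(sort(present)[1])
  fits <- lapply(present, fit_ref, theta = canonical$theta)
  names(fits) <- present
  want <- list(c("conserved", "lost"), c("conserved", "gained"),
               c("gained", "lost"))
  rows <- lapply(want, function(pair) {
    a <- pair[1]; b <- pair[2]
    if (!all(pair %in% present)) {
      warning("guild absent everywhere; omitting contrast ", a, " - ", b)
      return(NULL)
    }
    ## with b as the reference, the coefficient named a is mean(a) - mean(b)
    co <- fits[[b]]$coefficients
    r <- co[co$term == a, ]
    data.frame(comparison = paste(a, "-", b), value = r$estimate,
               se = r$se, t = r$t, df = r$df, p = r$p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
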