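## Pagel's lambda phylogenetic signal for a continuous trait: profiled
## multivariate-normal likelihood with the lambda transform applied to the
## Brownian covariance of the tree.

#' Brownian-motion covariance of a tree's tips
#'
#' `C[i, j]` is the shared root-to-MRCA path length of tips i and j (the
#' expected trait covariance under unit-rate Brownian motion);
#' `C[i, i]` is the tip's root-to-tip depth.
#'
#' @param tree a `phylo` object.
#' @return symmetric matrix over tips, dimnames = tip labels.
#' @export
brownian_vcv <- function(tree) {
  tree <- validate_phylogeny(tree)
  taxa <- tree$tip.label
  d <- node_depths(tree)[seq_along(taxa)]
  D <- patristic_matrix(tree, taxa)
  C <- (outer(d, d, "+") - D) / 2
  dimnames(C) <- list(taxa, taxa)
  C
}

lambda_vcv <- function(C, lambda) {
  V <- C * lambda
  diag(V) <- diag(C)
  V
}

## Profiled log-likelihood at a given lambda: mu and sigma^2 maximized
## analytically.
lambda_loglik <- function(lambda, C, x) {
  n <- length(x)
  V <- lambda_vcv(C, lambda)
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  one <- rep(1, n)
  Vi_x <- backsolve(R, backsolve(R, x, transpose = TRUE))
  Vi_1 <- backsolve(R, backsolve(R, one, transpose = TRUE))
  mu <- sum(Vi_x) / sum(Vi_1)
  r <- x - mu
  q <- sum(r * (Vi_x - mu * Vi_1))
  s2 <- q / n
  if (s2 <= 0) return(-Inf)
  -0.5 * (n * log(2 * pi * s2) + 2 * sum(log(diag(R))) + n)
}

#' Pagel's lambda for a continuous trait
#'
#' Maximum-likelihood estimate of lambda on `[0, 1]`, where lambda scales
#' the off-diagonal entries of the Brownian covariance (lambda = 0: no
#' phylogenetic signal, tips independent; lambda = 1: Brownian motion).
#' The mean and rate are profiled out analytically; the search combines a
#' golden-section/parabolic optimizer with explicit endpoint checks, ties
#' at a boundary resolving to the endpoint. Significance is a likelihood
#' ratio test against lambda = 0 on one degree of freedom, with p = 1 when
#' the estimate is at the zero boundary.
#'
#' @param tree a `phylo` object with at least 4 tips and positive depth.
#' @param x named numeric trait vector covering every tip.
#' @param trait optional trait name carried into the result.
#' @return object of class `nfix_lambda`: list with `lambda`, `logLik`,
#'   `logLik0` (at lambda = 0), `lrt`, `p`, `trait`, `n_tips`,
#'   `degenerate` (TRUE on a star tree, where the likelihood is flat).
#' @export
pagel_lambda <- function(tree, x, trait = deparse(substitute(x))) {
  tree <- validate_phylogeny(tree)
  n <- ape::Ntip(tree)
  if (n < 4L) stop("Pagel's lambda needs at least 4 tips")
  if (is.null(names(x))) stop("trait vector must be named by tip label")
  names(x) <- normalize_species(names(x))
  miss <- setdiff(tree$tip.label, names(x))
  if (length(miss))
    stop("trait missing for tips: ", paste(miss, collapse = ", "))
  x <- as.numeric(x[tree$tip.label])
  if (anyNA(x) || any(!is.finite(x))) stop("trait values must be finite")
  if (stats::sd(x) == 0)
    stop("trait is constant; lambda is unidentifiable")
  C <- brownian_vcv(tree)
  if (max(C[upper.tri(C)]) <= 1e-12 * max(diag(C))) {
    warning("star tree: likelihood is flat in lambda; reporting lambda = 0")
    l0 <- lambda_loglik(0, C, x)
    return(structure(list(lambda = 0, logLik = l0, logLik0 = l0, lrt = 0,
                          p = 1, trait = trait, n_tips = n,
                          degenerate = TRUE), class = "nfix_lambda"))
  }
  opt <- stats::optimize(function(l) lambda_loglik(l, C, x),
                         interval = c(0, 1), maximum = TRUE, tol = 1e-8)
  cand <- c(0, opt$maximum, 1)
  ll <- vapply(cand, lambda_loglik, numeric(1), C = C, x = x)
  ## ties resolve to the endpoint (index order puts endpoints first/last)
  best <- cand[which(ll >= max(ll) - 1e-10)]
  lambda <- if (any(best %in% c(0, 1))) best[best %in% c(0, 1)][1] else best[1]
  lhat <- lambda_loglik(lambda, C, x)
  l0 <- ll[1]
  lrt <- max(2 * (lhat - l0), 0)
  p <- if (lambda <= 1e-8) 1 else stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  structure(list(lambda = lambda, logLik = lhat, logLik0 = l0, lrt = lrt,
                 p = p, trait = trait, n_tips = n, degenerate = FALSE),
            class = "nfix_lambda")
}

#' @export
print.nfix_lambda <- function(x, ...) {
  cat(sprintf("Pagel's lambda for '%s' (%d tips): lambda = %.4f, LRT = %.3f, p = %.4g\n",
              x$trait, x$n_tips, x$lambda, x$lrt, x$p))
  invisible(x)
}

#' Phylogenetic signal in species-fate statistics
#'
#' Convenience wrapper computing Pagel's lambda for the loss probability,
#' gain probability and net plot-occupancy change of each species, on the
#' phylogeny pruned to the species in the fate table.
#'
#' @param tree phylogeny containing the fate-table species.
#' @param fates output of [species_fates()].
#' @return data frame `trait, lambda, logLik, logLik0, lrt, p, n_tips`.
#' @export
fate_phylosignal <- function(tree, fates) {
  sub <- prune_to_taxa(tree, fates$species)
  one <- function(col) {
    v <- stats::setNames(fates[[col]], fates$species)
    f <- pagel_lambda(sub, v, trait = col)
    data.frame(trait = col, lambda = f$lambda, logLik = f$logLik,
               logLik0 = f$logLik0, lrt = f$lrt, p = f$p, n_tips = f$n_tips)
  }
  out <- do.call(rbind, lapply(c("p_lost", "p_gained", "delta_p"), one))
  rownames(out) <- NULL
  out
}
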