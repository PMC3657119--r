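#' Gibbs sampler for the Bayesian normal linear model
#'
#' Samples the posterior of `y = X b + e`, `e ~ N(0, sigma2)`, under an
#' improper flat prior on the coefficients and an inverse-gamma
#' `IG(c0/2, d0/2)` prior on the error variance. The full conditionals are
#' conjugate: `b | sigma2 ~ N(b_ols, sigma2 (X'X)^-1)` and
#' `sigma2 | b ~ IG((c0 + n)/2, (d0 + SSR(b))/2)`, so the chain is a standard
#' two-block Gibbs sampler. The defaults (1000 burn-in, 10000 retained draws,
#' c0 = d0 = 0.001) reproduce the conventional vague-prior MCMC regression
#' setup used for credibility-interval estimation.
#'
#' @param y Response vector.
#' @param X Design matrix, full column rank, with `nrow(X) >= ncol(X) + 1`.
#' @param burnin Number of discarded initial iterations.
#' @param samples Number of retained draws.
#' @param seed Optional integer seed for reproducibility.
#' @param c0,d0 Inverse-gamma prior hyperparameters (shape and rate are
#'   `c0/2` and `d0/2`).
#' @return A `gibbs_fit` object: list with `beta` (samples x p matrix of
#'   coefficient draws), `sigma2` (vector of variance draws) and bookkeeping.
#' @export
gibbs_linear_regression <- function(y, X, burnin = 1000, samples = 10000,
                                    seed = NULL, c0 = 0.001, d0 = 0.001) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n) stop("rows(X) must equal length(y)", call. = FALSE)
  if (n < p + 1) stop("too few observations: need length(y) >= ncol(X) + 1",
                      call. = FALSE)
  if (qr(X)$rank < p) stop("design matrix is rank deficient", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  XtX <- crossprod(X)
  R <- chol(XtX)                       # X'X = R'R
  b_ols <- backsolve(R, forwardsolve(t(R), crossprod(X, y)))
  resid0 <- y - X %*% b_ols
  sigma2 <- max(sum(resid0^2) / max(n - p, 1), 1e-8)

  total <- burnin + samples
  beta_draws <- matrix(NA_real_, samples, p)
  sigma2_draws <- numeric(samples)
  shape <- (c0 + n) / 2
  for (it in seq_len(total)) {
    b <- b_ols + sqrt(sigma2) * backsolve(R, stats::rnorm(p))
    ssr <- sum((y - X %*% b)^2)
    sigma2 <- 1 / stats::rgamma(1, shape = shape, rate = (d0 + ssr) / 2)
    if (it > burnin) {
      beta_draws[it - burnin, ] <- b
      sigma2_draws[it - burnin] <- sigma2
    }
  }
  colnames(beta_draws) <- colnames(X)
  structure(list(beta = beta_draws, sigma2 = sigma2_draws, n = n,
                 burnin = burnin, samples = samples, c0 = c0, d0 = d0),
            class = "gibbs_fit")
}

#' @export
print.gibbs_fit <- function(x, ...) {
  cat(sprintf("<gibbs_fit> %d retained draws (%d burn-in), %d coefficient(s), n = %d\n",
              x$samples, x$burnin, ncol(x$beta), x$n))
  invisible(x)
}

#' Monte-Carlo standard error of a chain mean
#'
#' Naive standard error inflated by the lag-1 autocorrelation factor
#' `sqrt((1 + rho) / (1 - rho))`, adequate for the near-independent draws of
#' the conjugate Gibbs sampler.
#'
#' @param draws Numeric vector of posterior draws.
#' @return Monte-Carlo standard error of `mean(draws)`.
#' @export
mcse <- function(draws) {
  n <- length(draws)
  rho <- stats::cor(draws[-1], draws[-n])
  if (!is.finite(rho)) rho <- 0
  rho <- min(max(rho, -0.99), 0.99)
  stats::sd(draws) / sqrt(n) * sqrt((1 + rho) / (1 - rho))
}

summarize_draws <- function(draws) {
  q <- stats::quantile(draws, c(0.025, 0.975), names = FALSE)
  tibble::tibble(mean = mean(draws), ci_low = q[1], ci_high = q[2],
                 mcse = mcse(draws))
}

#' Posterior group means via zero-intercept cell-means regression
#'
#' Fits `y ~ 0 + group` (one indicator column per level, no global intercept)
#' with [gibbs_linear_regression()], so each coefficient is the posterior
#' group-level mean. Levels with fewer than two observations are excluded
#' with a warning.
#'
#' @param data Data frame.
#' @param response Name of the numeric response column.
#' @param group Name of the grouping column (coerced to factor).
#' @param ... Passed to [gibbs_linear_regression()] (`burnin`, `samples`,
#'   `seed`, priors).
#' @return A tibble with `level_label`, `mean`, `ci_low`, `ci_high`, `mcse`,
#'   `n_obs`.
#' @export
group_means <- function(data, response, group, ...) {
  y <- data[[response]]
  g <- factor(data[[group]])
  counts <- table(g)
  singles <- names(counts)[counts < 2]
  if (length(singles) > 0) {
    warning("excluding level(s) with fewer than 2 observations: ",
            paste(singles, collapse = ", "), call. = FALSE)
    keep <- !(as.character(g) %in% singles)
    y <- y[keep]
    g <- droplevels(g[keep])
  }
  if (nlevels(g) == 0) stop("no levels with >= 2 observations", call. = FALSE)
  # indicator column per level (cell-means coding, no global intercept)
  X <- vapply(levels(g), function(l) as.numeric(g == l), numeric(length(g)))
  X <- matrix(X, ncol = nlevels(g), dimnames = list(NULL, levels(g)))
  fit <- gibbs_linear_regression(y, X, ...)
  out <- dplyr::bind_rows(lapply(seq_len(ncol(X)), function(j) {
    s <- summarize_draws(fit$beta[, j])
    s$level_label <- colnames(X)[j]
    s$n_obs <- as.integer(sum(g == colnames(X)[j]))
    s
  }))
  out[, c("level_label", "mean", "ci_low", "ci_high", "mcse", "n_obs")]
}

#' Pairwise level differences via fitted-intercept regression
#'
#' For each baseline level, refits the model with a fitted intercept and
#' treatment coding (`y ~ group` with the baseline as reference), so each
#' non-baseline coefficient is the posterior difference between that level
#' and the baseline. Every unordered level pair appears once, as
#' `level_a - level_b` with `level_b` the earlier level in factor order. A
#' difference is flagged `credible` when its 95% credibility interval
#' excludes zero.
#'
#' @inheritParams group_means
#' @param seed Optional base seed; fit `i` uses `seed + i` so refits are
#'   reproducible but not identical.
#' @return A tibble with `level_a`, `level_b`, `diff_mean`, `diff_ci_low`,
#'   `diff_ci_high`, `mcse`, `credible`.
#' @export
pairwise_differences <- function(data, response, group, seed = NULL, ...) {
  y <- data[[response]]
  g <- factor(data[[group]])
  if (nlevels(g) < 2) stop("need at least 2 levels for pairwise comparison",
                           call. = FALSE)
  levs <- levels(g)
  rows <- list()
  for (b in seq_len(length(levs) - 1)) {
    g2 <- stats::relevel(g, ref = levs[b])
    X <- stats::model.matrix(~ g2)
    fit <- gibbs_linear_regression(y, X,
                                   seed = if (is.null(seed)) NULL else seed + b,
                                   ...)
    for (a in seq(b + 1, length(levs))) {
      draws <- fit$beta[, paste0("g2", levs[a])]
      s <- summarize_draws(draws)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        level_a = levs[a], level_b = levs[b],
        diff_mean = s$mean, diff_ci_low = s$ci_low, diff_ci_high = s$ci_high,
        mcse = s$mcse,
        credible = s$ci_low > 0 | s$ci_high < 0
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Format a pairwise comparison table in compact triangular layout
#'
#' Renders pairwise differences as `mean (ci_low, ci_high)` strings in a wide
#' lower-triangle layout (rows minus columns), the conventional presentation
#' of pairwise credibility-interval comparisons.
#'
#' @param pairs Output of [pairwise_differences()].
#' @return A tibble, one row per `level_a`, one column per `level_b`.
#' @export
format_pairwise <- function(pairs) {
  pairs$cell <- sprintf("%.1f (%.1f, %.1f)", pairs$diff_mean,
                        pairs$diff_ci_low, pairs$diff_ci_high)
  tidyr::pivot_wider(pairs[, c("level_a", "level_b", "cell")],
                     names_from = "level_b", values_from = "cell")
}
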