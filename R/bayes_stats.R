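# Conjugate Beta-binomial inference on detection proportions, highest
# density intervals, Monte Carlo difference posteriors, the 95%-HDI
# non-overlap significance rule, and a conjugate normal group-mean model
# sharing that decision rule. All HDIs are found by continuous
# optimization on the quantile scale, so they are deterministic.

#' Beta posterior/prior over a detection probability
#'
#' @param a,b Positive shape parameters.
#' @return Object of class `beta_posterior`.
#' @export
beta_posterior <- function(a, b) {
  if (a <= 0 || b <= 0) stop("shapes must be positive", call. = FALSE)
  structure(list(a = a, b = b), class = "beta_posterior")
}

#' @export
print.beta_posterior <- function(x, ...) {
  cat(sprintf("<Beta(%g, %g): mean %.3f>\n", x$a, x$b, x$a / (x$a + x$b)))
  invisible(x)
}

#' Conjugate Beta-binomial update
#'
#' `Beta(a, b)` prior with `k` detections in `n` trials gives
#' `Beta(a + k, b + n - k)`. Composition over batches equals a single
#' update on the pooled counts.
#'
#' @param prior A `beta_posterior` (e.g. `beta_posterior(5, 1)`, the
#'   default reporting prior encoding the expectation that most
#'   motoneurons show detectable potentials; `beta_posterior(1, 1)` is the
#'   flat alternative).
#' @param k Detections, `0 <= k <= n`.
#' @param n Trials.
#' @return A `beta_posterior`.
#' @examples
#' update_beta(beta_posterior(5, 1), 7, 26)   # Beta(12, 20)
#' @export
update_beta <- function(prior, k, n) {
  if (k < 0 || n < 0 || k > n) stop("need 0 <= k <= n", call. = FALSE)
  beta_posterior(prior$a + k, prior$b + n - k)
}

# Narrowest interval with `level` mass: minimize width of
# [qdist(p), qdist(p + level)] over p in [0, 1 - level].
hdi_continuous <- function(qdist, level = 0.95) {
  width <- function(p) qdist(p + level) - qdist(p)
  opt <- stats::optimize(width, c(0, 1 - level), tol = 1e-10)
  c(lower = qdist(opt$minimum), upper = qdist(opt$minimum + level))
}

#' Summarize a posterior
#'
#' Mean, median (inverse CDF), and highest density interval at `level`.
#' Percent reports use integer truncation (floor of 100 x value), the
#' convention under which a Beta(12, 20) mean of 0.375 reads 37% and a
#' Beta(24, 2) mean of 0.9231 reads 92%.
#'
#' @param posterior A `beta_posterior`, or a numeric vector of posterior
#'   draws (summarized empirically).
#' @param level HDI mass, in (0, 1).
#' @return List of class `posterior_summary`: `mean`, `median`, `hdi_low`,
#'   `hdi_high`, `level`, `mean_percent` (truncated integer),
#'   `hdi_percent` (truncated integers).
#' @export
summarize_posterior <- function(posterior, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  if (inherits(posterior, "beta_posterior")) {
    m <- posterior$a / (posterior$a + posterior$b)
    med <- stats::qbeta(0.5, posterior$a, posterior$b)
    hdi <- hdi_continuous(function(p) stats::qbeta(p, posterior$a, posterior$b),
                          level)
  } else {
    x <- as.numeric(posterior)
    m <- mean(x); med <- stats::median(x)
    sx <- sort(x)
    n_in <- ceiling(level * length(sx))
    starts <- seq_len(length(sx) - n_in + 1)
    widths <- sx[starts + n_in - 1] - sx[starts]
    i <- which.min(widths)
    hdi <- c(lower = sx[i], upper = sx[i + n_in - 1])
  }
  structure(list(mean = m, median = med,
                 hdi_low = unname(hdi[1]), hdi_high = unname(hdi[2]),
                 level = level,
                 mean_percent = trunc(100 * m),
                 hdi_percent = trunc(100 * unname(hdi))),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("<posterior: mean %.3f (%d%%), %g%% HDI [%.3f, %.3f]>\n",
              x$mean, x$mean_percent, 100 * x$level, x$hdi_low, x$hdi_high))
  invisible(x)
}

#' Posterior of a difference of detection probabilities
#'
#' Independent Monte Carlo draws from two Beta posteriors, differenced
#' elementwise; returns the draws, their summary, and the posterior
#' probability that the first proportion exceeds the second.
#'
#' @param p1,p2 `beta_posterior` objects.
#' @param n_draws Number of draws (a warning below 1000; the MC standard
#'   error is reported either way).
#' @param seed Integer seed.
#' @param level HDI level for the summary.
#' @return List: `draws`, `summary` (a `posterior_summary` of theta1 -
#'   theta2), `pr_greater`, `mc_se`.
#' @export
difference_posterior <- function(p1, p2, n_draws = 100000, seed = 1L,
                                 level = 0.95) {
  if (n_draws < 1000)
    warning("n_draws < 1000: Monte Carlo error will be large", call. = FALSE)
  set.seed(as.integer(seed))
  d <- stats::rbeta(n_draws, p1$a, p1$b) - stats::rbeta(n_draws, p2$a, p2$b)
  list(draws = d, summary = summarize_posterior(d, level),
       pr_greater = mean(d > 0),
       mc_se = stats::sd(d) / sqrt(n_draws))
}

#' HDI non-overlap significance rule
#'
#' Two groups differ "significantly" when their HDIs at the same level do
#' not overlap: the upper bound of the lower interval lies strictly below
#' the lower bound of the higher interval. Touching endpoints are not
#' significant.
#'
#' @param summary1,summary2 `posterior_summary` objects at equal levels.
#' @return List: `significant` (logical), `gap` (positive when disjoint).
#' @export
hdi_overlap_test <- function(summary1, summary2) {
  if (!isTRUE(all.equal(summary1$level, summary2$level)))
    stop("HDI levels differ", call. = FALSE)
  lo <- if (summary1$mean <= summary2$mean) summary1 else summary2
  hi <- if (summary1$mean <= summary2$mean) summary2 else summary1
  gap <- hi$hdi_low - lo$hdi_high
  list(significant = gap > 0, gap = gap)
}

#' Conjugate normal model for group means
#'
#' A closed-form Bayesian comparison of group means sharing the HDI
#' non-overlap decision rule: each group gets a Normal likelihood with a
#' weakly informative Normal-Inverse-Gamma conjugate prior (prior mean =
#' pooled mean, prior mean scale `kappa0`, variance prior centered on
#' `(prior_scale x pooled SD)^2` with half a degree of freedom). The
#' marginal posterior of each group mean is a scaled Student-t, whose HDI
#' is the equal-tailed interval by symmetry.
#'
#' @param values Numeric vector of observations.
#' @param groups Parallel group labels (2 groups for a decision; 1 allowed
#'   for a summary).
#' @param prior_scale Multiplier on the pooled SD for the variance prior.
#' @param level HDI level.
#' @param kappa0 Prior pseudo-observations on the mean.
#' @return List: `posteriors` (per group: `mean`, `df`, `scale`, and a
#'   `posterior_summary`), `decision` (from [hdi_overlap_test()], `NULL`
#'   unless exactly 2 groups).
#' @export
group_mean_model <- function(values, groups, prior_scale = 2.5,
                             level = 0.95, kappa0 = 0.01) {
  groups <- as.character(groups)
  if (any(table(groups) < 2))
    stop("each group needs at least 2 values", call. = FALSE)
  mu0 <- mean(values)
  s_pool <- stats::sd(values)
  a0 <- 0.5
  b0 <- 0.5 * (prior_scale * s_pool)^2
  posts <- lapply(split(values, groups), function(y) {
    n <- length(y); ybar <- mean(y)
    kn <- kappa0 + n
    mun <- (kappa0 * mu0 + n * ybar) / kn
    an <- a0 + n / 2
    bn <- b0 + 0.5 * sum((y - ybar)^2) +
      kappa0 * n * (ybar - mu0)^2 / (2 * kn)
    scale <- sqrt(bn / (an * kn))
    df <- 2 * an
    half <- stats::qt((1 + level) / 2, df) * scale
    summ <- structure(list(mean = mun, median = mun,
                           hdi_low = mun - half, hdi_high = mun + half,
                           level = level,
                           mean_percent = trunc(100 * mun),
                           hdi_percent = trunc(100 * c(mun - half, mun + half))),
                      class = "posterior_summary")
    list(mean = mun, df = df, scale = scale, summary = summ)
  })
  decision <- NULL
  if (length(posts) == 2)
    decision <- hdi_overlap_test(posts[[1]]$summary, posts[[2]]$summary)
  list(posteriors = posts, decision = decision)
}
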