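# Hierarchical Bayesian N-mixture model: site abundance N_i ~ Poisson(lambda_i)
# latent, counts y_ij | N_i ~ Binomial(N_i, p_ij) across replicate sources,
# logit(p_ij) = alpha_j + beta_j * z(h_i) with source-level intercepts and
# slopes on standardized human population. The discrete latent is summed out
# of the likelihood; sampling is adaptive random-walk Metropolis-within-Gibbs
# in compiled code, and N_i is reconstructed per retained draw from its exact
# conditional.

#' MCMC configuration for the N-mixture model
#'
#' @param n_iterations iterations per chain.
#' @param thin thinning interval.
#' @param burn_in iterations discarded before retention (and during which
#'   proposal scales adapt).
#' @param n_chains number of parallel chains (>= 2 for convergence
#'   diagnostics).
#' @param K_margin_quantile Poisson quantile used to set the per-site
#'   truncation bound of the marginalised sum.
#' @param p_floor smallest plausible per-source detection probability used to
#'   bound the truncation (`lambda_upper = max(y)/p_floor`).
#' @param lambda_mode `"site"` (site-specific lambda_i under a log-normal
#'   hierarchy; default), `"shared"` (the literal scalar-lambda reading), or
#'   `"site_regression"` (log-linear regression of lambda_i on z).
#' @param prior_spec priors: `mu_sd` (normal sd on the log-abundance mean),
#'   `sigma_lambda_scale`, `sigma_beta_scale` (half-normal scales),
#'   `gamma_sd` (regression-slope sd). Source intercepts alpha_j carry a
#'   standard-logistic prior, the Uniform(0,1) equivalent on the baseline
#'   detection probability scale.
#' @param seed integer seed; chains are jittered and run deterministically
#'   from it.
#' @return object of class `model_config`.
#' @export
model_config <- function(n_iterations = 100000L, thin = 50L,
                         burn_in = 10000L, n_chains = 2L,
                         K_margin_quantile = 0.999, p_floor = 0.15,
                         lambda_mode = c("site", "shared", "site_regression"),
                         prior_spec = list(mu_sd = 10, sigma_lambda_scale = 2.5,
                                           sigma_beta_scale = 1, gamma_sd = 5),
                         seed = 1L) {
  lambda_mode <- match.arg(lambda_mode)
  n_iterations <- as.integer(n_iterations); thin <- as.integer(thin)
  burn_in <- as.integer(burn_in); n_chains <- as.integer(n_chains)
  if (thin < 1L) stop("invalid parameter: thin must be >= 1")
  if (burn_in >= n_iterations)
    stop("invalid parameter: burn_in must be < n_iterations")
  if (n_chains < 2L)
    stop("invalid parameter: n_chains must be >= 2 for convergence diagnostics")
  if (K_margin_quantile <= 0 || K_margin_quantile >= 1)
    stop("invalid parameter: K_margin_quantile must be in (0, 1)")
  structure(list(n_iterations = n_iterations, thin = thin, burn_in = burn_in,
                 n_chains = n_chains, K_margin_quantile = K_margin_quantile,
                 p_floor = p_floor, lambda_mode = lambda_mode,
                 prior_spec = prior_spec, seed = as.integer(seed)),
            class = "model_config")
}

#' Marginal site log-likelihood with the latent abundance summed out
#'
#' Computes `log sum_{N = max(y)}^{K} Poisson(N; lambda) prod_j
#' Binomial(y_j; N, p_j)` in log space with stable summation over the full
#' truncation range.
#'
#' @param y_row integer counts for one site across sources.
#' @param lambda_i expected abundance at the site (> 0).
#' @param p detection probabilities per source (in `[0, 1]`), or a list with
#'   elements `alpha`, `beta`, `z` giving the logit-linear detection row.
#' @param K truncation bound (>= `max(y_row)`).
#' @return the marginal log-likelihood (scalar).
#' @export
marginal_site_loglik <- function(y_row, lambda_i, p, K) {
  if (is.list(p)) p <- plogis(p$alpha + p$beta * p$z)
  y_row <- as.integer(y_row)
  if (K < max(y_row)) stop("invalid parameter: K must be at least max(y_row)")
  if (lambda_i <= 0) stop("invalid parameter: lambda_i must be > 0")
  if (any(p < 0 | p > 1)) stop("invalid parameter: p must lie in [0, 1]")
  site_marginal_loglik_cpp(y_row, lambda_i, as.numeric(p), as.integer(K))
}

#' Truncation bound for the marginalised abundance sum
#'
#' `K = max(Poisson quantile q at lambda_upper, max(y) + 50)`; the floor of
#' `max(y) + 50` guarantees headroom even for tiny rates, and K is
#' non-decreasing in `q`.
#'
#' @param y_row counts at the site.
#' @param lambda_upper an upper bound on plausible abundance.
#' @param q Poisson quantile in (0, 1).
#' @return integer truncation bound.
#' @export
choose_truncation <- function(y_row, lambda_upper, q = 0.999) {
  if (q <= 0 || q >= 1) stop("invalid parameter: q must be in (0, 1)")
  m <- max(as.numeric(y_row))
  as.integer(max(qpois(q, lambda_upper), m + 50))
}

#' Simulate a count matrix from the N-mixture model itself
#'
#' Used for parameter-recovery and coverage experiments: draws
#' `N_i ~ Poisson(lambda_i)` and `y_ij ~ Binomial(N_i, plogis(alpha_j +
#' beta_j z_i))`.
#'
#' @param lambda site expected abundances.
#' @param alpha,beta source detection intercepts and slopes (logit scale).
#' @param z standardized covariate per site.
#' @param seed optional seed (RNG state is restored afterwards).
#' @return list with `y` (sites x sources), `N`, `p`.
#' @export
simulate_count_matrix <- function(lambda, alpha, beta, z, seed = NULL) {
  sim <- function() {
    S <- length(lambda); J <- length(alpha)
    N <- rpois(S, lambda)
    p <- plogis(outer(z, beta) + matrix(alpha, S, J, byrow = TRUE))
    y <- matrix(rbinom(S * J, rep(N, J), as.vector(p)), S, J)
    rownames(y) <- sprintf("S%02d", seq_len(S))
    colnames(y) <- sprintf("SRC%02d", seq_len(J))
    list(y = y, N = N, p = p)
  }
  if (is.null(seed)) sim() else with_seed(seed, sim())
}

#' Fit the hierarchical N-mixture model
#'
#' Runs `config$n_chains` adaptive Metropolis-within-Gibbs chains over the
#' marginalised posterior. Initialisation: `lambda_i` at `max_j y_ij / 0.5`,
#' `alpha_j` at the logit of a crude per-source detection fraction, `beta_j`
#' at 0, jittered per chain from the seed; a non-finite likelihood at
#' initialisation triggers re-jittered restarts up to 10 times.
#'
#' @param y a `count_matrix` (or plain matrix with area rownames).
#' @param geo a `geography_map` supplying the human-population covariate
#'   (matched to rownames of `y`); alternatively pass `covariate` directly.
#' @param config a [model_config()].
#' @param covariate optional numeric covariate per site, overriding `geo`.
#' @return object of class `posterior_draws`: list of per-chain draw matrices
#'   (`lambda[...]`, `alpha[...]`, `beta[...]`, hyperparameters, `N[...]`),
#'   plus site/source ids, truncation bounds, covariate transform and config.
#' @export
fit_nmixture <- function(y, geo = NULL, config = model_config(),
                         covariate = NULL) {
  y <- unclass(y)
  storage.mode(y) <- "integer"
  S <- nrow(y); J <- ncol(y)
  site_ids <- rownames(y) %||% sprintf("S%02d", seq_len(S))
  source_ids <- colnames(y) %||% sprintf("SRC%02d", seq_len(J))
  if (is.null(covariate)) {
    if (is.null(geo)) stop("supply geo or covariate")
    gi <- match(site_ids, geo$area)
    if (anyNA(gi)) stop("sites not in geography map: ",
                        paste(site_ids[is.na(gi)], collapse = ", "))
    covariate <- geo$human_population[gi]
  }
  if (any(!is.finite(covariate))) stop("covariate must be finite")
  z <- standardize_covariate(covariate)

  maxy <- apply(y, 1, max)
  K <- vapply(seq_len(S), function(i)
    choose_truncation(y[i, ], max(maxy[i], 1) / config$p_floor,
                      config$K_margin_quantile), integer(1))

  lam_hat <- pmax(maxy, 1) / 0.5
  p_hat <- pmin(pmax(colMeans(y / lam_hat), 0.02), 0.9)
  pr <- config$prior_spec
  mode_code <- match(config$lambda_mode,
                     c("site", "shared", "site_regression")) - 1L
  nlam <- if (config$lambda_mode == "shared") 1L else S

  chains <- vector("list", config$n_chains)
  accept_log <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    res <- NULL
    for (try in 1:10) {
      res <- with_seed(derive_seed(config$seed, 100L * ch + try), {
        loglam0 <- log(if (nlam == 1L) mean(lam_hat) else lam_hat) +
          rnorm(nlam, 0, 0.1)
        alpha0 <- qlogis(p_hat) + rnorm(J, 0, 0.1)
        beta0 <- rnorm(J, 0, 0.05)
        nmix_mcmc_cpp(y, as.numeric(z), K,
                      config$n_iterations, config$burn_in, config$thin,
                      loglam0, alpha0, beta0,
                      mean(loglam0), 0.5, 0.3, 0, mode_code,
                      pr$mu_sd, pr$sigma_lambda_scale, pr$sigma_beta_scale,
                      pr$gamma_sd %||% 5, TRUE)
      })
      if (isTRUE(res$ok)) break
    }
    if (!isTRUE(res$ok))
      stop("non-finite likelihood at initialization after retries")
    dm <- res$draws
    lam_names <- if (nlam == 1L) "lambda" else paste0("lambda[", site_ids, "]")
    nm <- c(lam_names, paste0("alpha[", source_ids, "]"),
            paste0("beta[", source_ids, "]"),
            "mu_lambda", "sigma_lambda", "sigma_beta",
            if (mode_code == 2L) "gamma",
            paste0("N[", site_ids, "]"))
    colnames(dm) <- nm
    chains[[ch]] <- dm
    accept_log[[ch]] <- res$log_scales
  }
  structure(list(chains = chains, site_ids = site_ids,
                 source_ids = source_ids, K = K, y = y,
                 z_center = attr(z, "center"), z_scale = attr(z, "scale"),
                 config = config, log_scales = accept_log),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("<posterior_draws>", length(x$chains), "chains x",
      nrow(x$chains[[1]]), "retained draws,", length(x$site_ids), "sites\n")
  invisible(x)
}

#' Split-chain Gelman-Rubin convergence diagnostic
#'
#' Potential scale reduction factor per scalar parameter, computed on chains
#' split in half (so within-chain drift also inflates the statistic). The
#' conventional convergence threshold used by the package is R-hat < 1.05.
#'
#' @param draws a `posterior_draws`, or a list of draw matrices with matching
#'   columns.
#' @param split split each chain in half before computing (default TRUE).
#' @return named numeric vector of R-hat values, with attribute `converged`
#'   (all R-hat < 1.05).
#' @export
gelman_rubin <- function(draws, split = TRUE) {
  chains <- if (inherits(draws, "posterior_draws")) draws$chains else draws
  if (!is.list(chains) || length(chains) < 2L)
    stop("at least two chains are required")
  n <- nrow(chains[[1]])
  if (n < 4L) stop("need at least 4 retained draws per chain")
  if (split) {
    h <- floor(n / 2)
    chains <- unlist(lapply(chains, function(m)
      list(m[seq_len(h), , drop = FALSE],
           m[(n - h + 1):n, , drop = FALSE])), recursive = FALSE)
  }
  m <- length(chains); n <- nrow(chains[[1]])
  rhat <- vapply(seq_len(ncol(chains[[1]])), function(k) {
    x <- vapply(chains, function(cm) cm[, k], numeric(n))
    mu <- colMeans(x)
    W <- mean(apply(x, 2, stats::var))
    B <- n * stats::var(mu)
    if (W == 0) return(if (B == 0) 1 else Inf)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
  names(rhat) <- colnames(chains[[1]])
  attr(rhat, "converged") <- all(rhat < 1.05)
  rhat
}

#' Summarise posterior abundance at a spatial level
#'
#' Aggregation is applied per draw (site abundances summed within each group,
#' then summarised), preserving posterior dependence; region draws therefore
#' sum exactly to country draws. Credible intervals are equal-tailed
#' 2.5/97.5 percentiles.
#'
#' @param draws a `posterior_draws`.
#' @param level `"site"`, `"region"`, `"country"`, or `"uk"` (overall total).
#' @param geo a `geography_map` (needed for region/country levels).
#' @return data.frame with `group`, `mean`, `median`, `lower`, `upper`.
#' @export
posterior_summary <- function(draws, level = c("site", "region", "country",
                                               "uk"), geo = NULL) {
  level <- match.arg(level)
  Nd <- draw_matrix(draws, "N")
  groups <- switch(level,
    site = draws$site_ids,
    region = ,
    country = {
      if (is.null(geo)) stop("geo is required for level '", level, "'")
      gi <- match(draws$site_ids, geo$area)
      if (anyNA(gi)) stop("sites not in geography map")
      geo[[level]][gi]
    },
    uk = rep("UK", length(draws$site_ids)))
  agg <- sapply(split(seq_along(groups), groups), function(ix)
    rowSums(Nd[, ix, drop = FALSE]))
  if (is.null(dim(agg))) agg <- matrix(agg, nrow = 1,
                                       dimnames = list(NULL, names(agg)))
  data.frame(group = colnames(agg),
             mean = colMeans(agg),
             median = apply(agg, 2, median),
             lower = apply(agg, 2, quantile, 0.025, names = FALSE),
             upper = apply(agg, 2, quantile, 0.975, names = FALSE),
             row.names = NULL)
}

# Pooled draw matrix (chains stacked) for a parameter family prefix
# ("N", "lambda", "alpha", "beta") or exact column names.
draw_matrix <- function(draws, family) {
  stopifnot(inherits(draws, "posterior_draws"))
  cols <- grep(paste0("^", family, "(\\[|$)"), colnames(draws$chains[[1]]))
  if (!length(cols)) stop("no such parameter family: ", family)
  do.call(rbind, lapply(draws$chains, function(m) m[, cols, drop = FALSE]))
}
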