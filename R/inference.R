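# Bayesian robust mixed-effects inference: censored Student-t regression
# with subject random intercepts fitted by MCMC (JAGS), posterior summaries
# with 99% credibility intervals, derived contrasts, and a robust Bayesian
# correlation matrix for the covariates.

#' Transform raw covariates to the model scale
#'
#' Applies the standard covariate transforms: `log10_tcne = log10(tcne)`
#' (one log10 unit = a tenfold difference in lifetime noise exposure
#' energy), `mus = music_years^(1/3)` (cube root tames the right skew), and
#' centers/scales the continuous predictors, storing the scalers for
#' inversion.
#'
#' @param data `data.frame`; columns `tcne` and/or `music_years` are
#'   transformed if present.
#' @param standardize Character vector of columns to center and scale into
#'   `<col>_std` companions (silently skipping absent ones).
#' @return The augmented `data.frame` with attribute `scalers`
#'   (`data.frame` of column, center, scale).
#' @export
transform_covariates <- function(data,
                                 standardize = c("age", "pta_0p5_2", "pta_4_12",
                                                 "pta_1_2", "log10_tcne", "mus")) {
  if ("tcne" %in% names(data)) {
    if (any(data$tcne <= 0)) stop("`tcne` must be positive")
    data$log10_tcne <- log10(data$tcne)
  }
  if ("music_years" %in% names(data)) {
    if (any(data$music_years < 0)) stop("`music_years` must be nonnegative")
    data$mus <- data$music_years^(1 / 3)
  }
  cols <- intersect(standardize, names(data))
  scalers <- data.frame(column = cols,
                        center = vapply(cols, function(cl) mean(data[[cl]]), 0),
                        scale = vapply(cols, function(cl) stats::sd(data[[cl]]), 0))
  for (cl in cols)
    data[[paste0(cl, "_std")]] <-
      (data[[cl]] - scalers$center[scalers$column == cl]) /
      scalers$scale[scalers$column == cl]
  attr(data, "scalers") <- scalers
  data
}

#' @rdname transform_covariates
#' @param x Standardized values to map back to the raw scale.
#' @param scalers The `scalers` attribute of a transformed table.
#' @param column Which column's scaler to invert.
#' @export
invert_standardization <- function(x, scalers, column) {
  s <- scalers[scalers$column == column, ]
  if (nrow(s) != 1L) stop("no scaler stored for column ", column)
  x * s$scale + s$center
}

#' Model specification for the outcome families
#'
#' Captures the regression structure of one outcome family: the response
#' column, the fixed-effect columns (factors expand to dummies via
#' `model.matrix`), the subject grouping column, and &mdash; for the
#' amplitude families &mdash; the censoring columns and the log transform.
#'
#' @param response Response column name.
#' @param fixed Character vector of fixed-effect terms (column names or
#'   interaction terms in formula syntax).
#' @param subject Subject (random-intercept) column name.
#' @param censored Name of the logical censoring flag column, or `NULL` for
#'   uncensored families.
#' @param bound Name of the censoring-bound column (same units as the raw
#'   response).
#' @param log_response Model `log(response)` (amplitude families) instead of
#'   the raw response.
#' @return List of class `model_spec`.
#' @export
model_spec <- function(response, fixed, subject = "subject", censored = NULL,
                       bound = "censor_bound", log_response = FALSE) {
  structure(list(response = response, fixed = fixed, subject = subject,
                 censored = censored, bound = bound,
                 log_response = log_response),
            class = "model_spec")
}

censored_lmm_code <- function(has_censored) {
  paste0("model {
  for (i in 1:Nobs) {
    yobs[i] ~ dt(inprod(Xobs[i, ], beta) + u[sobs[i]], tauy, nu)
  }
", if (has_censored) "  for (j in 1:Ncens) {
    # censoring (not truncation): the indicator observed at 0 contributes
    # the probability mass below the bound to the likelihood
    cens_ind[j] ~ dinterval(ycen[j], ubound[j])
    ycen[j] ~ dt(inprod(Xcen[j, ], beta) + u[scen[j]], tauy, nu)
  }
" else "", "  for (s in 1:S) { u[s] ~ dnorm(0, tauu) }
  for (p in 1:P) { beta[p] ~ dnorm(0, beta_prec) }
  sigma ~ dunif(0, sigma_upper)
  tauy <- pow(sigma, -2)
  sigma_u ~ dunif(0, sigma_u_upper)
  tauu <- pow(sigma_u, -2)
  nu <- 2 + nu_excess
  nu_excess ~ dexp(nu_rate)
}")
}

#' Fit a censored robust mixed-effects regression by MCMC
#'
#' The observation model is Student-t (robust, df a free parameter bounded
#' below at 2) around a linear predictor with subject random intercepts.
#' Rows flagged censored contribute the probability mass below their bound:
#' each censored response is a latent t-distributed node whose interval
#' indicator is observed at 0 (below the bound), which marginalizes to the
#' censored likelihood. Priors are weakly informative:
#' `beta ~ N(0, prior_beta_sd^2)` (predictors are expected standardized),
#' uniform scale priors, exponential prior on the t df excess over 2.
#'
#' @param data Measurement table.
#' @param spec A [model_spec()].
#' @param n_chains,n_adapt,n_iter MCMC configuration.
#' @param seed Integer seed (chains are seeded `seed + 1, seed + 2, ...`).
#' @param prob Credibility-interval mass (default 0.99).
#' @param prior_beta_sd,prior_sigma_upper,prior_nu_rate Prior hyperparameters.
#' @param rhat_threshold Convergence flag threshold on the potential scale
#'   reduction factor.
#' @return List of class `censored_lmm_fit`: `draws` (a `coda::mcmc.list` of
#'   the fixed effects and variance parameters), `summary` (a
#'   [posterior_summary()] table), `converged`, `coef_names`, `spec`.
#' @export
fit_model <- function(data, spec, n_chains = 2, n_adapt = 500, n_iter = 1500,
                      seed = 1, prob = 0.99, prior_beta_sd = 10,
                      prior_sigma_upper = 10, prior_nu_rate = 1 / 28,
                      rhat_threshold = 1.05) {
  stopifnot(inherits(spec, "model_spec"))
  y <- data[[spec$response]]
  cens <- if (!is.null(spec$censored)) as.logical(data[[spec$censored]])
          else rep(FALSE, nrow(data))
  cens[is.na(cens)] <- FALSE
  bound <- if (!is.null(spec$censored)) data[[spec$bound]] else rep(NA_real_, nrow(data))
  if (spec$log_response) {
    y <- ifelse(cens, NA_real_, log(y))
    bound <- log(bound)
  } else if (any(cens)) {
    y[cens] <- NA_real_
  }
  if (any(!cens & !is.finite(y))) stop("non-finite response in uncensored rows")
  X <- stats::model.matrix(
    stats::reformulate(spec$fixed),
    data = data)
  subj <- factor(data[[spec$subject]])
  jd <- list(Nobs = sum(!cens), Xobs = X[!cens, , drop = FALSE],
             yobs = y[!cens], sobs = as.integer(subj)[!cens],
             S = nlevels(subj), P = ncol(X),
             beta_prec = 1 / prior_beta_sd^2,
             sigma_upper = prior_sigma_upper,
             sigma_u_upper = prior_sigma_upper,
             nu_rate = prior_nu_rate)
  has_cens <- any(cens)
  if (has_cens) {
    jd$Ncens <- sum(cens)
    jd$Xcen <- X[cens, , drop = FALSE]
    jd$scen <- as.integer(subj)[cens]
    jd$ubound <- bound[cens]
    jd$cens_ind <- rep(0L, sum(cens))
  }
  inits <- lapply(seq_len(n_chains), function(ch) {
    ini <- list(beta = rep(0, ncol(X)), sigma = 0.5, sigma_u = 0.5,
                nu_excess = 10,
                .RNG.name = "base::Mersenne-Twister",
                .RNG.seed = as.integer(seed + ch))
    if (has_cens) ini$ycen <- jd$ubound - 0.1
    ini
  })
  model <- rjags::jags.model(textConnection(censored_lmm_code(has_cens)),
                             data = jd, inits = inits, n.chains = n_chains,
                             n.adapt = n_adapt, quiet = TRUE)
  stats::update(model, n.iter = max(200, n_adapt), progress.bar = "none")
  draws <- rjags::coda.samples(model, c("beta", "sigma", "sigma_u", "nu"),
                               n.iter = n_iter, progress.bar = "none")
  draws <- rename_beta(draws, colnames(X))
  summ <- posterior_summary(draws, prob = prob,
                            rhat_threshold = rhat_threshold)
  structure(list(draws = draws, summary = summ,
                 converged = all(is.na(summ$rhat) | summ$rhat <= rhat_threshold),
                 coef_names = colnames(X), spec = spec),
            class = "censored_lmm_fit")
}

rename_beta <- function(draws, coef_names) {
  vn <- coda::varnames(draws)
  bet <- grepl("^beta\\[", vn)
  idx <- as.integer(sub("beta\\[(\\d+)\\]", "\\1", vn[bet]))
  vn[bet] <- coef_names[idx]
  for (i in seq_along(draws)) colnames(draws[[i]]) <- vn
  draws
}

#' @export
print.censored_lmm_fit <- function(x, ...) {
  cat(sprintf("<censored_lmm_fit> %d coefficients, %s\n",
              length(x$coef_names),
              if (x$converged) "converged" else "NOT converged"))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Summarize posterior draws
#'
#' Posterior median, central credibility interval (default 99%), effective
#' sample size and potential-scale-reduction diagnostic for every monitored
#' parameter. Summaries are invariant to chain order (all chains are pooled
#' for the quantiles).
#'
#' @param draws A `coda::mcmc.list`.
#' @param prob Interval mass.
#' @param rhat_threshold Parameters with Rhat above this are flagged.
#' @return `data.frame` with columns `parameter`, `median`, `lower`,
#'   `upper`, `ess`, `rhat`, `flagged`.
#' @export
posterior_summary <- function(draws, prob = 0.99, rhat_threshold = 1.05) {
  m <- as.matrix(draws)
  a <- (1 - prob) / 2
  q <- t(apply(m, 2, stats::quantile, probs = c(a, 0.5, 1 - a)))
  ess <- tryCatch(coda::effectiveSize(draws), error = function(e) rep(NA, ncol(m)))
  rhat <- rep(NA_real_, ncol(m))
  if (coda::nchain(draws) >= 2) {
    gd <- tryCatch(coda::gelman.diag(draws, multivariate = FALSE,
                                     autoburnin = FALSE)$psrf[, 1],
                   error = function(e) rep(NA_real_, ncol(m)))
    rhat <- gd
  }
  data.frame(parameter = colnames(m), median = q[, 2], lower = q[, 1],
             upper = q[, 3], ess = as.numeric(ess), rhat = as.numeric(rhat),
             flagged = !is.na(rhat) & rhat > rhat_threshold,
             row.names = NULL)
}

#' Percentage amplitude change per age decade
#'
#' Maps per-year slopes on the natural-log amplitude scale to the percentage
#' change for a 10-year age increase, `100 (exp(10 beta) - 1)`, applied
#' drawwise so summaries come from the transformed posterior.
#'
#' @param beta Per-year log-scale slope draws (or a scalar).
#' @return Percent change per decade, same shape as `beta`.
#' @export
percent_change_per_decade <- function(beta) 100 * (expm1(10 * beta))

#' Extract draws of a named coefficient
#'
#' @param fit A `censored_lmm_fit`.
#' @param coef Coefficient (column) name.
#' @return Numeric vector of pooled posterior draws.
#' @export
coef_draws <- function(fit, coef) {
  m <- as.matrix(fit$draws)
  if (!coef %in% colnames(m))
    stop("no coefficient named ", coef, "; available: ",
         paste(colnames(m), collapse = ", "))
  m[, coef]
}

#' Derived drawwise contrasts
#'
#' Differences of coefficient draws, computed drawwise and summarized after
#' an optional transform (e.g. [percent_change_per_decade()] for log-scale
#' slope differences such as the high/low-level amplitude-ratio age effect,
#' or identity for dB-scale modulation-depth differences).
#'
#' @param fit A `censored_lmm_fit`.
#' @param contrasts Named list, each element `c(coef_a, coef_b)` meaning
#'   `coef_a - coef_b`.
#' @param transform Function applied drawwise before summarizing.
#' @param prob Credibility-interval mass.
#' @return `data.frame` of posterior medians and intervals, one row per
#'   contrast.
#' @export
derived_contrasts <- function(fit, contrasts, transform = identity,
                              prob = 0.99) {
  a <- (1 - prob) / 2
  out <- lapply(names(contrasts), function(nm) {
    cc <- contrasts[[nm]]
    d <- transform(coef_draws(fit, cc[1]) - coef_draws(fit, cc[2]))
    q <- stats::quantile(d, probs = c(a, 0.5, 1 - a))
    data.frame(contrast = nm, median = q[[2]], lower = q[[1]], upper = q[[3]])
  })
  do.call(rbind, out)
}

#' Robust Bayesian correlation matrix
#'
#' Posterior of the full correlation matrix of a covariate table under a
#' multivariate Student-t model, written as the usual Gaussian scale
#' mixture: `y_i ~ N(mu, (lambda_i Omega)^-1)` with
#' `lambda_i ~ Gamma(nu/2, nu/2)`, a `Wishart(I, P + 1)` prior on the
#' precision `Omega`, a vague normal prior on `mu`, and a discrete uniform
#' prior on the df grid `nu_grid` (robustness to outlying subjects). All
#' full conditionals are conjugate, so the posterior is sampled by a Gibbs
#' sampler. Columns are standardized internally, which leaves correlations
#' unchanged.
#'
#' @param data Numeric `data.frame`/matrix of covariates (complete rows
#'   only; >= 3 required).
#' @param n_iter,n_burn Gibbs iterations kept / discarded.
#' @param nu_grid Support of the discrete df prior.
#' @param seed Integer seed.
#' @param prob Credibility-interval mass.
#' @return `data.frame` with one row per variable pair: `var1`, `var2`,
#'   `median`, `lower`, `upper`, plus attribute `draws` (iterations x
#'   pairs). A near-singular posterior (|median| > 0.999) triggers a
#'   degeneracy warning.
#' @export
bayes_correlation_matrix <- function(data, n_iter = 2000, n_burn = 500,
                                     nu_grid = c(2.5, 3, 4, 6, 8, 12, 20, 30, 50),
                                     seed = 1, prob = 0.99) {
  y <- as.matrix(data)
  y <- y[stats::complete.cases(y), , drop = FALSE]
  n <- nrow(y)
  if (n < 3) stop("need at least 3 complete rows")
  sds <- apply(y, 2, stats::sd)
  if (any(sds == 0)) stop("constant column: correlation undefined")
  y <- scale(y)
  r_emp <- stats::cor(y)
  if (max(abs(r_emp[upper.tri(r_emp)])) > 0.999)
    warning("near-degenerate input: some columns are (almost) collinear; ",
            "their correlation posterior is boundary-dominated")
  P <- ncol(y)
  vn <- colnames(y)
  if (is.null(vn)) vn <- paste0("V", seq_len(P))
  pairs <- utils::combn(P, 2)
  npair <- ncol(pairs)
  tau0 <- 0.01 # prior precision on mu (data are standardized)
  with_local_seed(seed, {
    mu <- colMeans(y)
    Omega <- diag(P)
    lambda <- rep(1, n)
    nu <- 8
    keep <- matrix(NA_real_, n_iter, npair)
    colnames(keep) <- paste(vn[pairs[1, ]], vn[pairs[2, ]], sep = ":")
    for (it in seq_len(n_burn + n_iter)) {
      e <- sweep(y, 2, mu)
      # lambda_i | . ~ Gamma((nu + P)/2, (nu + e_i' Omega e_i)/2)
      d2 <- rowSums((e %*% Omega) * e)
      lambda <- stats::rgamma(n, (nu + P) / 2, rate = (nu + d2) / 2)
      # Omega | . ~ Wishart(n + P + 1, (I + sum lambda_i e_i e_i')^-1)
      S <- crossprod(e * sqrt(lambda))
      Omega <- stats::rWishart(1, n + P + 1, solve(diag(P) + S))[, , 1]
      # mu | . ~ N(M^-1 Omega sum(lambda_i y_i), M^-1), M = tau0 I + sum(lambda) Omega
      M <- tau0 * diag(P) + sum(lambda) * Omega
      Mi <- solve(M)
      mmean <- Mi %*% (Omega %*% colSums(y * lambda))
      mu <- drop(mmean + t(chol(Mi)) %*% stats::rnorm(P))
      # nu | lambda on the grid
      loglik <- vapply(nu_grid, function(v)
        n * (v / 2 * log(v / 2) - lgamma(v / 2)) +
          (v / 2 - 1) * sum(log(lambda)) - v / 2 * sum(lambda), 0)
      pr <- exp(loglik - max(loglik))
      nu <- nu_grid[sample.int(length(nu_grid), 1, prob = pr)]
      if (it > n_burn) {
        Sigma <- solve(Omega)
        s <- sqrt(diag(Sigma))
        R <- Sigma / tcrossprod(s)
        keep[it - n_burn, ] <- R[cbind(pairs[1, ], pairs[2, ])]
      }
    }
    a <- (1 - prob) / 2
    out <- do.call(rbind, lapply(seq_len(npair), function(j) {
      qq <- stats::quantile(keep[, j], probs = c(a, 0.5, 1 - a))
      data.frame(var1 = vn[pairs[1, j]], var2 = vn[pairs[2, j]],
                 median = qq[[2]], lower = qq[[1]], upper = qq[[3]])
    }))
    if (any(abs(out$median) > 0.999))
      warning("near-degenerate correlation posterior (|median| > 0.999)")
    attr(out, "draws") <- keep
    out
  })
}
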