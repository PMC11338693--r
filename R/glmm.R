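#' Model specifications for the two monitoring GLMMs
#'
#' `growth_model_spec()` describes the Gaussian mixed model for group-level
#' annual population growth rates: fixed effects for standardized prey
#' index, elevation, their interaction and snow depth, plus a transect-group
#' random intercept and a residual SD. `abundance_model_spec()` describes the
#' negative-binomial mixed model for per-visit track counts: the same four
#' covariates plus mature-spruce and agricultural kernel densities, the log
#' survey effort (transect length times days since snowfall) as an offset
#' with coefficient 1, a year random intercept, and dispersion `theta`
#' (variance `mu + mu^2/theta`).
#'
#' Priors (weakly informative): Normal(0, `prior_sd`^2) on the intercept and
#' all slopes (default SD 2); half-Normal(0, 2) on the residual and
#' random-intercept SDs; Exponential(1) on `1/theta`.
#'
#' @param fixed Character vector of covariate column names (standardized by
#'   the caller); the intercept is always included.
#' @param response Response column name.
#' @param group Random-intercept grouping column, or `NULL` for none.
#' @param offset Log-scale offset column (abundance model only), or `NULL`.
#' @param prior_sd Prior SD for intercept and slopes.
#' @param fixed_sigma For the Gaussian model, a known residual SD to condition
#'   on instead of sampling it (used mainly for validation against conjugate
#'   closed forms); default `NULL` samples it.
#' @return A list of class `"marten_model_spec"`.
#' @export
growth_model_spec <- function(fixed = c("rodent", "elevation",
                                        "rodent_x_elevation", "snow"),
                              response = "growth_rate", group = "group_id",
                              prior_sd = 2, fixed_sigma = NULL) {
  structure(list(type = "gaussian", fixed = fixed, response = response,
                 group = group, offset = NULL, prior_sd = prior_sd,
                 fixed_sigma = fixed_sigma),
            class = "marten_model_spec")
}

#' @rdname growth_model_spec
#' @export
abundance_model_spec <- function(fixed = c("rodent", "elevation",
                                           "rodent_x_elevation", "snow",
                                           "spruce", "agri"),
                                 response = "tracks", group = "year",
                                 offset = "offset_log", prior_sd = 2) {
  structure(list(type = "nb", fixed = fixed, response = response,
                 group = group, offset = offset, prior_sd = prior_sd,
                 fixed_sigma = NULL),
            class = "marten_model_spec")
}

#' Simulate data exactly from the abundance model
#'
#' Generates a model-ready dataset from the negative-binomial track-count
#' model itself: independent standardized covariates, survey effort drawn
#' from the truncated-normal effort distributions of the monitoring design
#' (length ~ N(2.93, 0.51^2) km truncated above 0.5; days ~ N(3.70, 1.65^2)
#' truncated at 1), years assigned round-robin, and centred year random
#' intercepts. Because the data-generating process coincides with the
#' fitted model, posterior parameter recovery on this data isolates the
#' correctness of the likelihood, priors and sampler from any confounding
#' present in a full synthetic world.
#'
#' @param n Number of transect-year rows.
#' @param delta Length-7 coefficient vector (intercept; rodent, elevation,
#'   rodent x elevation, snow, spruce, agri slopes).
#' @param theta NB dispersion (> 0).
#' @param year_effect_sd SD of the (centred) year random intercept.
#' @param n_years Number of year levels.
#' @param seed Integer seed.
#' @return List with `data` (model-ready data frame for
#'   [abundance_model_spec()]) and `truth` (`delta`, `theta`, `v_year`).
#' @export
simulate_abundance_data <- function(n = 3000,
                                    delta = c(-3.4, 0.566, 0.425, 0.160,
                                              0.463, 0.369, -0.129),
                                    theta = 2, year_effect_sd = 0.3,
                                    n_years = 10, seed = 1L) {
  stopifnot(length(delta) == 7, theta > 0, n_years >= 2)
  set.seed(seed)
  z <- function() z_standardize(stats::rnorm(n))$z
  d <- data.frame(rodent = z(), elevation = z(), snow = z(),
                  spruce = z(), agri = z())
  d$rodent_x_elevation <- d$rodent * d$elevation
  d$year <- 2000L + (seq_len(n) %% n_years) + 1L
  v <- stats::rnorm(n_years, 0, year_effect_sd)
  v <- stats::setNames(v - mean(v), sort(unique(d$year)))
  len <- rtruncnorm(n, 2.93, 0.51, lower = 0.5)
  days <- rtruncnorm(n, 3.70, 1.65, lower = 1)
  d$offset_log <- log(len) + log(days)
  X <- cbind(1, d$rodent, d$elevation, d$rodent_x_elevation, d$snow,
             d$spruce, d$agri)
  eta <- d$offset_log + as.vector(X %*% delta) + v[as.character(d$year)]
  d$tracks <- stats::rnbinom(n, mu = exp(eta), size = theta)
  d <- d[, c("tracks", "rodent", "elevation", "rodent_x_elevation", "snow",
             "spruce", "agri", "year", "offset_log")]
  list(data = d, truth = list(delta = delta, theta = theta, v_year = v))
}

# assemble the numerical pieces of a model once
model_context <- function(spec, data) {
  data <- as.data.frame(data)
  need <- c(spec$response, spec$fixed, spec$group, spec$offset)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing model column(s): ", paste(miss, collapse = ", "))
  if (nrow(data) > 0 && anyNA(data[, need])) stop("missing values in model rows")
  y <- data[[spec$response]]
  if (spec$type == "nb") {
    if (any(y < 0) || any(y != round(y))) stop("counts must be non-negative integers")
  }
  X <- cbind(`(Intercept)` = rep(1, nrow(data)))
  for (f in spec$fixed) X <- cbind(X, data[[f]])
  colnames(X) <- c("(Intercept)", spec$fixed)
  if (nrow(data) > 0 && qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  off <- if (!is.null(spec$offset)) data[[spec$offset]] else rep(0, nrow(data))
  if (!is.null(spec$offset) && any(!is.finite(off))) {
    stop("offsets must be finite (were they logged after checking positivity?)")
  }
  grp <- NULL; levels_g <- character(0)
  if (!is.null(spec$group)) {
    grp <- factor(data[[spec$group]])
    levels_g <- levels(grp)
    if (nrow(data) > 0 && length(levels_g) < 2) {
      stop("need >= 2 groups to identify the random-intercept SD")
    }
  }
  par_names <- c(colnames(X),
                 if (length(levels_g)) paste0("u[", levels_g, "]"),
                 if (spec$type == "gaussian" && is.null(spec$fixed_sigma)) "sigma",
                 if (spec$type == "nb") "theta",
                 if (length(levels_g)) "sigma_group")
  list(spec = spec, y = y, X = X, offset = off,
       grp_idx = if (!is.null(grp)) as.integer(grp) else NULL,
       levels_g = levels_g, n = nrow(data), p = ncol(X),
       K = length(levels_g), par_names = par_names)
}

# per-row log likelihood; disp is sigma (gaussian) or theta (nb)
loglik_rows <- function(ctx, eta, disp) {
  if (ctx$n == 0) return(numeric(0))
  if (ctx$spec$type == "gaussian") {
    stats::dnorm(ctx$y, eta, disp, log = TRUE)
  } else {
    stats::dnbinom(ctx$y, size = disp, mu = exp(eta), log = TRUE)
  }
}

linpred <- function(ctx, beta, u) {
  eta <- as.vector(ctx$X %*% beta) + ctx$offset
  if (ctx$K) eta <- eta + u[ctx$grp_idx]
  eta
}

lp_beta <- function(beta, prior_sd) sum(stats::dnorm(beta, 0, prior_sd, log = TRUE))
lp_u <- function(u, sigma_g) sum(stats::dnorm(u, 0, sigma_g, log = TRUE))
# half-Normal(0,2) prior on a SD sampled on the log scale (Jacobian included)
lp_halfnorm_log <- function(log_s) {
  stats::dnorm(exp(log_s), 0, 2, log = TRUE) + log(2) + log_s
}
# Exponential(1) on 1/theta, theta sampled on the log scale
lp_invtheta_log <- function(log_theta) {
  phi <- exp(-log_theta)
  -phi + log(phi)
}

#' Joint log posterior of a monitoring GLMM
#'
#' Log likelihood plus log priors for a parameter vector. Parameters are
#' supplied as a named list: `beta` (intercept + slopes, in the order
#' `c("(Intercept)", spec$fixed)`), `u` (random intercepts, one per group
#' level), and the positive scalars `sigma` (Gaussian residual SD),
#' `theta` (NB dispersion), `sigma_group` (random-intercept SD) as
#' applicable. Returns `-Inf` outside the support.
#'
#' @param spec A `"marten_model_spec"`.
#' @param params Named list of parameter values (see details).
#' @param data Model-ready data frame.
#' @return Scalar log posterior density (unnormalized).
#' @export
log_posterior <- function(spec, params, data) {
  ctx <- model_context(spec, data)
  beta <- params$beta
  if (length(beta) != ctx$p) stop("beta must have length ", ctx$p)
  u <- if (ctx$K) params$u else numeric(0)
  if (ctx$K && length(u) != ctx$K) stop("u must have length ", ctx$K)
  disp <- if (spec$type == "gaussian") {
    if (!is.null(spec$fixed_sigma)) spec$fixed_sigma else params$sigma
  } else params$theta
  if (!is.null(disp) && (!is.finite(disp) || disp <= 0)) return(-Inf)
  sigma_g <- if (ctx$K) params$sigma_group else NULL
  if (ctx$K && (!is.finite(sigma_g) || sigma_g <= 0)) return(-Inf)
  lp <- sum(loglik_rows(ctx, linpred(ctx, beta, u), disp)) +
    lp_beta(beta, spec$prior_sd)
  if (ctx$K) {
    lp <- lp + lp_u(u, sigma_g) + lp_halfnorm_log(log(sigma_g))
  }
  if (spec$type == "gaussian" && is.null(spec$fixed_sigma)) {
    lp <- lp + lp_halfnorm_log(log(disp))
  }
  if (spec$type == "nb") lp <- lp + lp_invtheta_log(log(disp))
  lp
}

#' Fit a monitoring GLMM by adaptive MCMC
#'
#' Samples the posterior defined by [log_posterior()] with a blockwise
#' adaptive random-walk Metropolis sampler: the fixed effects move jointly
#' under a proposal covariance adapted to the posterior during warmup
#' (several proposals per stored iteration), random intercepts are updated
#' one group at a time with per-group adapted step sizes (valid as a single
#' vectorized sweep because the likelihood factorizes over groups), and the
#' scalar SD/dispersion parameters take log-scale random-walk steps. All
#' adaptation is frozen at the end of warmup, so the post-warmup chain is a
#' valid Markov chain. Defaults follow common practice for these models:
#' 4 chains of 6000 iterations with the first 3000 discarded as warmup.
#'
#' @param spec A `"marten_model_spec"`.
#' @param data Model-ready data frame (standardized covariates; for the
#'   abundance model an `offset_log` column with log(length x days)).
#' @param chains,iterations,warmup MCMC settings.
#' @param seed Integer seed; chain `c` uses stream `seed + 1000 * c`, and the
#'   full draw sequence is reproducible.
#' @param beta_repeats Fixed-effect block proposals per iteration (more
#'   repeats cost likelihood evaluations but cut autocorrelation).
#' @param prior_only If `TRUE` the likelihood is switched off and the
#'   sampler draws from the prior (for prior predictive and calibration
#'   checks).
#' @return An object of class `"marten_fit"`: posterior draws
#'   (`iterations - warmup` x `chains` x parameters array), per-parameter
#'   posterior means, 80% equal-tailed credible intervals and
#'   "excludes zero" flags, split R-hat and bulk effective sample sizes,
#'   sampler settings, and a `convergence_warning` flag. A warning is
#'   emitted (never silenced) if any R-hat >= 1.01.
#' @export
fit_model <- function(spec, data, chains = 4, iterations = 6000,
                      warmup = 3000, seed = 1L, beta_repeats = 8,
                      prior_only = FALSE) {
  stopifnot(inherits(spec, "marten_model_spec"), warmup < iterations)
  ctx <- model_context(spec, data)
  if (ctx$n == 0 && !prior_only) stop("no data rows; use prior_only = TRUE to sample the prior")
  n_keep <- iterations - warmup
  p <- ctx$p; K <- ctx$K
  sample_sigma <- spec$type == "gaussian" && is.null(spec$fixed_sigma)
  npar <- p + K + as.integer(sample_sigma) + as.integer(spec$type == "nb") +
    as.integer(K > 0)
  draws <- array(NA_real_, dim = c(n_keep, chains, npar),
                 dimnames = list(NULL, NULL, ctx$par_names))

  ll_fun <- function(eta, disp) {
    if (prior_only || ctx$n == 0) 0 else sum(loglik_rows(ctx, eta, disp))
  }
  ll_rows_fun <- function(eta, disp) {
    if (prior_only || ctx$n == 0) rep(0, ctx$n) else loglik_rows(ctx, eta, disp)
  }

  for (ch in seq_len(chains)) {
    set.seed(seed + 1000L * ch)
    beta <- stats::rnorm(p, 0, 0.1)
    u <- if (K) stats::rnorm(K, 0, 0.1) else numeric(0)
    log_disp <- 0            # log sigma or log theta
    log_sigma_g <- log(0.5)
    disp <- if (spec$type == "gaussian" && !is.null(spec$fixed_sigma)) {
      spec$fixed_sigma
    } else exp(log_disp)
    eta <- linpred(ctx, beta, u)
    ll <- ll_fun(eta, disp)

    # adaptation state
    prop_chol <- diag(0.1, p)
    lsc_beta <- 0; acc_beta <- 0; try_beta <- 0
    warm_beta <- matrix(NA_real_, warmup, p)
    ls_u <- rep(log(0.5), K); acc_u <- rep(0, K); try_u <- 0
    ls_disp <- log(0.3); acc_disp <- 0; try_disp <- 0
    ls_sg <- log(0.5); acc_sg <- 0; try_sg <- 0
    ls_nc <- log(0.5); acc_nc <- 0; try_nc <- 0

    for (it in seq_len(iterations)) {
      adapting <- it <= warmup

      ## fixed-effect block
      for (r in seq_len(beta_repeats)) {
        prop <- beta + exp(lsc_beta) * as.vector(crossprod(prop_chol, stats::rnorm(p)))
        eta_p <- eta + as.vector(ctx$X %*% (prop - beta))
        ll_p <- ll_fun(eta_p, disp)
        d <- ll_p - ll + lp_beta(prop, spec$prior_sd) - lp_beta(beta, spec$prior_sd)
        try_beta <- try_beta + 1
        if (is.finite(d) && log(stats::runif(1)) < d) {
          beta <- prop; eta <- eta_p; ll <- ll_p; acc_beta <- acc_beta + 1
        }
      }

      ## random-intercept sweep (one accept/reject per group)
      if (K) {
        sigma_g <- exp(log_sigma_g)
        u_prop <- u + exp(ls_u) * stats::rnorm(K)
        if (prior_only || ctx$n == 0) {
          d_g <- rep(0, K)
        } else {
          eta_p <- eta + (u_prop - u)[ctx$grp_idx]
          lr_cur <- ll_rows_fun(eta, disp)
          lr_prop <- ll_rows_fun(eta_p, disp)
          d_g <- as.vector(rowsum(lr_prop - lr_cur, ctx$grp_idx,
                                  reorder = TRUE))
        }
        d_g <- d_g + stats::dnorm(u_prop, 0, sigma_g, log = TRUE) -
          stats::dnorm(u, 0, sigma_g, log = TRUE)
        acc <- is.finite(d_g) & log(stats::runif(K)) < d_g
        u[acc] <- u_prop[acc]
        eta <- linpred(ctx, beta, u)
        ll <- ll_fun(eta, disp)
        acc_u <- acc_u + acc; try_u <- try_u + 1

        ## exact Gibbs move along the translation degeneracy
        ## (intercept + c, u - c leaves the likelihood unchanged; the
        ## conditional of c under the Gaussian priors is Gaussian)
        sigma_g <- exp(log_sigma_g)
        prec <- 1 / spec$prior_sd^2 + K / sigma_g^2
        mc <- (-beta[1] / spec$prior_sd^2 + sum(u) / sigma_g^2) / prec
        cshift <- stats::rnorm(1, mc, 1 / sqrt(prec))
        beta[1] <- beta[1] + cshift
        u <- u - cshift

        ## centered sigma_group update (no likelihood term, so several
        ## cheap MH steps per iteration keep its autocorrelation low)
        for (r in 1:5) {
          prop_lsg <- log_sigma_g + exp(ls_sg) * stats::rnorm(1)
          d <- lp_u(u, exp(prop_lsg)) + lp_halfnorm_log(prop_lsg) -
            lp_u(u, exp(log_sigma_g)) - lp_halfnorm_log(log_sigma_g)
          try_sg <- try_sg + 1
          if (is.finite(d) && log(stats::runif(1)) < d) {
            log_sigma_g <- prop_lsg; acc_sg <- acc_sg + 1
          }
        }

        ## interweaved non-centered update: hold u / sigma_group fixed and
        ## move sigma_group against the likelihood — this is the move that
        ## mixes when the group variance collapses towards zero (funnel)
        ut <- u / exp(log_sigma_g)
        prop_lsg <- log_sigma_g + exp(ls_nc) * stats::rnorm(1)
        u_prop <- ut * exp(prop_lsg)
        eta_p <- eta + (u_prop - u)[ctx$grp_idx]
        ll_p <- ll_fun(eta_p, disp)
        d <- ll_p - ll + lp_halfnorm_log(prop_lsg) - lp_halfnorm_log(log_sigma_g)
        try_nc <- try_nc + 1
        if (is.finite(d) && log(stats::runif(1)) < d) {
          log_sigma_g <- prop_lsg; u <- u_prop; eta <- eta_p; ll <- ll_p
          acc_nc <- acc_nc + 1
        }
      }

      ## dispersion scalar
      if (sample_sigma || spec$type == "nb") {
        prop_ld <- log_disp + exp(ls_disp) * stats::rnorm(1)
        prop_disp <- exp(prop_ld)
        ll_p <- ll_fun(eta, prop_disp)
        pr <- if (spec$type == "nb") {
          lp_invtheta_log(prop_ld) - lp_invtheta_log(log_disp)
        } else {
          lp_halfnorm_log(prop_ld) - lp_halfnorm_log(log_disp)
        }
        d <- ll_p - ll + pr
        try_disp <- try_disp + 1
        if (is.finite(d) && log(stats::runif(1)) < d) {
          log_disp <- prop_ld; disp <- prop_disp; ll <- ll_p
          acc_disp <- acc_disp + 1
        }
      }

      ## adaptation (warmup only)
      if (adapting) {
        warm_beta[it, ] <- beta
        if (it %% 50 == 0) {
          step <- min(0.2, 2 / sqrt(it / 50))
          lsc_beta <- lsc_beta + step * (acc_beta / try_beta - 0.234)
          acc_beta <- 0; try_beta <- 0
          if (K) {
            ls_u <- ls_u + step * (acc_u / try_u - 0.44)
            acc_u[] <- 0; try_u <- 0
            ls_sg <- ls_sg + step * (acc_sg / try_sg - 0.44)
            acc_sg <- 0; try_sg <- 0
            ls_nc <- ls_nc + step * (acc_nc / try_nc - 0.44)
            acc_nc <- 0; try_nc <- 0
          }
          if (sample_sigma || spec$type == "nb") {
            ls_disp <- ls_disp + step * (acc_disp / try_disp - 0.44)
            acc_disp <- 0; try_disp <- 0
          }
          if (it >= 200 && p > 1) {
            S <- stats::cov(warm_beta[seq_len(it), , drop = FALSE])
            ch_try <- tryCatch(chol(S + diag(1e-10, p)), error = function(e) NULL)
            if (!is.null(ch_try)) {
              prop_chol <- ch_try * (2.38 / sqrt(p))
              lsc_beta <- 0
            }
          }
        }
      }

      if (it > warmup) {
        row <- c(beta, u,
                 if (sample_sigma) exp(log_disp),
                 if (spec$type == "nb") exp(log_disp),
                 if (K) exp(log_sigma_g))
        draws[it - warmup, ch, ] <- row
      }
    }
  }

  rh <- apply(draws, 3, function(m) rhat_split(m))
  es <- apply(draws, 3, function(m) ess_bulk(m))
  flat <- matrix(aperm(draws, c(1, 2, 3)), nrow = n_keep * chains,
                 dimnames = list(NULL, ctx$par_names))
  post_mean <- colMeans(flat)
  ci <- t(apply(flat, 2, stats::quantile, probs = c(0.1, 0.9)))
  summary_df <- data.frame(
    parameter = ctx$par_names, mean = unname(post_mean),
    cri_lower = unname(ci[, 1]), cri_upper = unname(ci[, 2]),
    excludes_zero = unname(ci[, 1] > 0 | ci[, 2] < 0),
    rhat = unname(rh), ess_bulk = unname(es),
    stringsAsFactors = FALSE
  )
  conv_warn <- any(rh >= 1.01, na.rm = TRUE)
  if (conv_warn) {
    warning(sprintf("possible non-convergence: max split R-hat = %.3f", max(rh, na.rm = TRUE)))
  }
  structure(list(draws = draws, spec = spec, data = data,
                 par_names = ctx$par_names, summary = summary_df,
                 rhat = stats::setNames(rh, ctx$par_names),
                 ess_bulk = stats::setNames(es, ctx$par_names),
                 convergence_warning = conv_warn,
                 settings = list(chains = chains, iterations = iterations,
                                 warmup = warmup, seed = seed,
                                 beta_repeats = beta_repeats,
                                 prior_only = prior_only)),
            class = "marten_fit")
}

#' @export
print.marten_fit <- function(x, ...) {
  cat(sprintf("<marten_fit> %s model: %d chains x %d post-warmup draws\n",
              x$spec$type, dim(x$draws)[2], dim(x$draws)[1]))
  df <- x$summary
  df[, 2:4] <- round(df[, 2:4], 3)
  df$rhat <- round(df$rhat, 4)
  df$ess_bulk <- round(df$ess_bulk)
  print(df, row.names = FALSE)
  if (x$convergence_warning) cat("** convergence warning: some R-hat >= 1.01 **\n")
  invisible(x)
}

# split R-hat on an iterations x chains matrix
rhat_split <- function(m) {
  n <- nrow(m)
  half <- floor(n / 2)
  sub <- cbind(m[seq_len(half), , drop = FALSE],
               m[(n - half + 1):n, , drop = FALSE])
  nn <- nrow(sub)
  mu <- colMeans(sub)
  if (stats::var(as.vector(sub)) == 0) return(1)
  B <- nn * stats::var(mu)
  W <- mean(apply(sub, 2, stats::var))
  if (W == 0) return(Inf)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# bulk effective sample size (combined-chain autocorrelation with Geyer's
# initial positive sequence truncation)
ess_bulk <- function(m, max_lag = 500L) {
  n <- nrow(m); cn <- ncol(m)
  if (stats::var(as.vector(m)) == 0) return(NA_real_)
  max_lag <- min(max_lag, n - 2L)
  acov <- sapply(seq_len(cn), function(c) {
    stats::acf(m[, c], lag.max = max_lag, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1]
  })
  W <- mean(acov[1, ]) * n / (n - 1)
  mu <- colMeans(m)
  var_plus <- (n - 1) / n * W + (if (cn > 1) stats::var(mu) else 0)
  rho <- 1 - (W - rowMeans(acov) * n / (n - 1)) / var_plus
  rho[1] <- 1
  # Geyer initial positive sequence: sum lag pairs while positive
  rho_lag <- rho[-1]
  tau <- 1
  for (mm in seq_len(floor(length(rho_lag) / 2))) {
    pair <- rho_lag[2 * mm - 1] + rho_lag[2 * mm]
    if (!is.finite(pair) || pair < 0) break
    tau <- tau + 2 * pair
  }
  n * cn / tau
}

#' Equal-tailed credible intervals from posterior draws
#'
#' @param draws A `"marten_fit"`, a draws matrix (iterations x parameters)
#'   or a numeric vector of draws for one parameter.
#' @param level Credibility level; default 0.80 (quantiles 0.10 and 0.90).
#'   `level = 1` returns the min/max of the draws.
#' @return Data frame `parameter`, `lower`, `upper`, `excludes_zero`.
#' @export
credible_interval <- function(draws, level = 0.80) {
  if (inherits(draws, "marten_fit")) {
    m <- apply(draws$draws, 3, as.vector)
  } else if (is.vector(draws) && is.numeric(draws)) {
    m <- matrix(draws, ncol = 1, dimnames = list(NULL, "parameter"))
  } else {
    m <- as.matrix(draws)
  }
  if (nrow(m) < 100) stop("need >= 100 draws for a stable interval")
  a <- (1 - level) / 2
  q <- apply(m, 2, stats::quantile, probs = c(a, 1 - a))
  out <- data.frame(parameter = colnames(m),
                    lower = unname(q[1, ]), upper = unname(q[2, ]),
                    stringsAsFactors = FALSE)
  out$excludes_zero <- out$lower > 0 | out$upper < 0
  out
}

#' Posterior predictive check
#'
#' Simulates replicate datasets from thinned posterior draws and places each
#' observed summary statistic within its replicate distribution. A
#' well-calibrated model yields quantile positions away from 0 and 1.
#'
#' @param fit A `"marten_fit"`.
#' @param stats Named list of statistic functions of the response vector;
#'   defaults to mean, SD and (for counts) the proportion of zeros.
#' @param n_rep Number of replicate datasets (thinned evenly over draws).
#' @param seed Integer seed for the replicate simulations.
#' @return Data frame `statistic`, `observed`, `rep_mean`, `quantile` (the
#'   probability a replicate statistic falls below the observed one).
#' @export
posterior_predictive_check <- function(fit, stats = NULL, n_rep = 200,
                                       seed = 1L) {
  spec <- fit$spec
  ctx <- model_context(spec, fit$data)
  if (is.null(stats)) {
    stats <- list(mean = mean, sd = stats::sd)
    if (spec$type == "nb") stats$prop_zero <- function(y) mean(y == 0)
  }
  flat <- apply(fit$draws, 3, as.vector)
  idx <- unique(round(seq(1, nrow(flat), length.out = n_rep)))
  set.seed(seed)
  obs <- vapply(stats, function(f) f(ctx$y), numeric(1))
  reps <- matrix(NA_real_, length(idx), length(stats),
                 dimnames = list(NULL, names(stats)))
  for (i in seq_along(idx)) {
    par <- flat[idx[i], ]
    beta <- par[seq_len(ctx$p)]
    u <- if (ctx$K) par[ctx$p + seq_len(ctx$K)] else numeric(0)
    eta <- linpred(ctx, beta, u)
    y_rep <- if (spec$type == "gaussian") {
      sg <- if (!is.null(spec$fixed_sigma)) spec$fixed_sigma else par[["sigma"]]
      stats::rnorm(ctx$n, eta, sg)
    } else {
      stats::rnbinom(ctx$n, mu = exp(eta), size = par[["theta"]])
    }
    reps[i, ] <- vapply(stats, function(f) f(y_rep), numeric(1))
  }
  data.frame(statistic = names(stats), observed = unname(obs),
             rep_mean = unname(colMeans(reps)),
             quantile = unname(vapply(seq_along(stats), function(j) {
               mean(reps[, j] < obs[j]) + 0.5 * mean(reps[, j] == obs[j])
             }, numeric(1))),
             stringsAsFactors = FALSE)
}
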