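# Bayesian hierarchical models of migration metrics on standardized
# game-farm ancestry: one univariate model per response, identity link for
# gaussian responses and log link for Poisson (stopover count) and
# negative-binomial (stopover duration) responses, with individual and
# migration-year random intercepts. Sampling is MCMC via JAGS with per-chain
# seeded RNGs, so fits are exactly reproducible.

#' Two-standard-deviation standardization of a predictor
#'
#' Centers `x` and divides by twice its sample standard deviation (n - 1
#' denominator), so the scaled predictor has mean 0 and SD 0.5 and
#' coefficients are comparable to those of a binary predictor.
#'
#' @param x numeric vector with positive variance.
#' @return list: `x_std`, `mean`, `sd` (the untransformed SD).
#' @examples
#' standardize_predictor(c(0, 0.1, 0.2))$x_std  # -0.5, 0, 0.5
#' @export
standardize_predictor <- function(x) {
  if (any(!is.finite(x))) stop("predictor contains non-finite values")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("predictor has no variance")
  m <- mean(x)
  list(x_std = (x - m) / (2 * s), mean = m, sd = s)
}

#' Probability of direction
#'
#' Share of posterior draws on the dominant side of zero, expressed on the
#' 50-100% scale; draws equal to zero are split evenly between the sides.
#'
#' @param draws numeric vector of posterior draws.
#' @return scalar in \[50, 100\].
#' @export
probability_of_direction <- function(draws) {
  stopifnot(length(draws) > 0)
  p0 <- mean(draws == 0)
  p_pos <- mean(draws > 0) + p0 / 2
  100 * max(p_pos, 1 - p_pos)
}

#' Rank-normalized split-chain potential scale reduction
#'
#' Gelman-Rubin convergence diagnostic computed on rank-normalized draws
#' after splitting each chain in half. Values near 1 indicate the chains
#' have mixed; the package flags parameters with values of 1.1 or more.
#'
#' @param chains iterations-by-chains numeric matrix, or a list of equal
#'   length numeric vectors (one per chain). At least 2 chains after
#'   splitting (i.e. at least 1 chain of length >= 4).
#' @return scalar R-hat.
#' @export
rhat <- function(chains) {
  if (is.list(chains)) {
    if (length(unique(lengths(chains))) != 1)
      stop("chains must have equal lengths")
    chains <- do.call(cbind, chains)
  }
  stopifnot(is.matrix(chains), nrow(chains) >= 4)
  n2 <- floor(nrow(chains) / 2)
  split <- cbind(chains[seq_len(n2), , drop = FALSE],
                 chains[seq(nrow(chains) - n2 + 1, nrow(chains)),
                        , drop = FALSE])
  if (length(unique(as.vector(split))) == 1L) {
    warning("all draws identical; R-hat undefined, returning 1")
    return(1)
  }
  S <- length(split)
  z <- stats::qnorm((rank(split, ties.method = "average") - 0.375) /
                    (S + 0.25))
  z <- matrix(z, nrow = n2)
  W <- mean(apply(z, 2, stats::var))
  B <- n2 * stats::var(colMeans(z))
  if (W == 0) return(1)
  sqrt(((n2 - 1) / n2 * W + B / n2) / W)
}

#' Classify the support for an ancestry effect
#'
#' Applies the credible-interval and probability-of-direction rules: a 90%
#' CrI excluding zero is a supported effect ("meaningful" when pd >= 95,
#' the value an equal-tailed 90% interval excluding zero implies,
#' "moderate" otherwise); a CrI straddling zero with pd < 89 is "none";
#' a CrI straddling zero with pd >= 89 is reported as "indeterminate" (both
#' facts are kept, the rules give no verdict). A non-converged fit is
#' always "indeterminate".
#'
#' @param cri_low,cri_high equal-tailed credible interval bounds.
#' @param pd probability of direction, 50-100.
#' @param converged logical; `FALSE` forces "indeterminate".
#' @return one of `"meaningful"`, `"moderate"`, `"none"`, `"indeterminate"`.
#' @export
classify_effect <- function(cri_low, cri_high, pd, converged = TRUE) {
  stopifnot(cri_low <= cri_high, pd >= 50, pd <= 100)
  if (!converged) return("indeterminate")
  excludes <- cri_low > 0 || cri_high < 0
  if (excludes) return(if (pd >= 95) "meaningful" else "moderate")
  if (pd < 89) "none" else "indeterminate"
}

jags_model_string <- function(family, random_effects, fixed_sigma) {
  lik <- switch(family,
    gaussian = "    y[i] ~ dnorm(eta[i], tau)",
    poisson = "    y[i] ~ dpois(mu[i])\n    log(mu[i]) <- eta[i]",
    negative_binomial = paste0(
      "    y[i] ~ dnegbin(p[i], r)\n",
      "    p[i] <- r / (r + mu[i])\n",
      "    log(mu[i]) <- eta[i]"))
  # year intercepts are hierarchically centered on alpha (w_k = alpha + v_k),
  # which removes the alpha/year-mean random walk under Gibbs sampling
  eta <- if (random_effects)
    "    eta[i] <- w[yr[i]] + beta * x[i] + u[ind[i]]"
  else
    "    eta[i] <- alpha + beta * x[i]"
  # individual intercepts use parameter expansion, u_j = xi_u * e_j with
  # e_j ~ N(0, 1/tau_eu) and tau_eu ~ Gamma(3/2, 3/2): the implied prior on
  # sd_u = |xi_u|/sqrt(tau_eu) is exactly half-Student-t(3, 0, scale_s),
  # and the sampler no longer sticks when sd_u is near zero
  re <- if (random_effects) paste0(
    "  for (j in 1:J) {\n",
    "    e_u[j] ~ dnorm(0, tau_eu)\n",
    "    u[j] <- xi_u * e_u[j]\n",
    "  }\n",
    "  xi_u ~ dnorm(0, pow(scale_s, -2))\n",
    "  tau_eu ~ dgamma(1.5, 1.5)\n",
    "  sd_u <- abs(xi_u) / sqrt(tau_eu)\n",
    "  for (k in 1:K) { w[k] ~ dnorm(alpha, tau_v) }\n",
    "  sd_v ~ dt(0, pow(scale_s, -2), 3) T(0,)\n",
    "  tau_v <- pow(sd_v, -2)\n") else ""
  disp <- switch(family,
    gaussian = if (is.null(fixed_sigma))
      paste0("  sigma ~ dt(0, pow(scale_s, -2), 3) T(0,)\n",
             "  tau <- pow(sigma, -2)\n")
    else "  tau <- pow(sigma_fixed, -2)\n",
    poisson = "",
    negative_binomial = "  r ~ dgamma(0.01, 0.01)\n")
  paste0("model {\n  for (i in 1:N) {\n", lik, "\n", eta, "\n  }\n",
         re, disp,
         "  alpha ~ dnorm(0, prec_ab)\n",
         "  beta ~ dnorm(0, prec_ab)\n}\n")
}

#' Fit one ancestry model
#'
#' Fits a univariate Bayesian regression of one migration metric on
#' 2-SD-standardized game-farm ancestry with individual and migration-year
#' random intercepts (each collapses with a warning when fewer than two
#' levels are present). Priors are weakly informative: Normal(0, (10 sd(y))^2)
#' on intercept and slope for gaussian responses (Normal(0, 10^2) under a
#' log link), half-Student-t(3, 0, 2.5 sd(y)) (or 2.5 under a log link) on
#' the random-effect and residual SDs, and Gamma(0.01, 0.01) on the
#' negative-binomial dispersion.
#'
#' @param data phenology data frame (see [compute_phenology()]); rows with a
#'   missing response are dropped and counted.
#' @param response column name of the response.
#' @param family `"gaussian"`, `"poisson"` or `"negative_binomial"`.
#' @param chains,iter,burn_in MCMC layout; `iter - burn_in` draws are kept
#'   per chain.
#' @param ci_level credible-interval mass (default 0.90, equal-tailed).
#' @param seed integer; chain RNGs are derived from it, so fits are exactly
#'   reproducible.
#' @param random_effects set `FALSE` to drop both random intercepts (used
#'   for closed-form cross-checks).
#' @param fixed_sigma optional known residual SD for gaussian fits (fixes
#'   the likelihood scale instead of sampling it).
#' @param label display name of the model.
#' @return object of class `ancestry_fit`.
#' @export
fit_ancestry_model <- function(data, response,
                               family = c("gaussian", "poisson",
                                          "negative_binomial"),
                               chains = 4, iter = 10000, burn_in = 4000,
                               ci_level = 0.90, seed = 1L,
                               random_effects = TRUE, fixed_sigma = NULL,
                               label = response) {
  family <- match.arg(family)
  stopifnot(burn_in < iter, response %in% names(data),
            "gamefarm_fraction" %in% names(data))
  keep <- is.finite(data[[response]])
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(sprintf("dropping %d row(s) with missing %s", n_dropped,
                    response))
  data <- data[keep, , drop = FALSE]
  y <- data[[response]]
  if (family != "gaussian") {
    if (any(y < 0)) stop("count responses must be non-negative")
    y <- as.integer(round(y))
  }
  std <- standardize_predictor(data$gamefarm_fraction)
  ind <- factor(data$individual_id)
  yr <- factor(data$migration_year)
  use_re <- random_effects
  if (use_re && (nlevels(ind) < 2 || nlevels(yr) < 2)) {
    warning("fewer than 2 individuals or years; random effects collapsed")
    use_re <- FALSE
  }

  jd <- list(y = y, x = std$x_std, N = length(y),
             prec_ab = if (family == "gaussian")
               (10 * stats::sd(y))^-2 else 1 / 100)
  if (use_re) {
    jd$ind <- as.integer(ind)
    jd$yr <- as.integer(yr)
    jd$J <- nlevels(ind)
    jd$K <- nlevels(yr)
  }
  if (use_re || (family == "gaussian" && is.null(fixed_sigma)))
    jd$scale_s <- if (family == "gaussian") 2.5 * stats::sd(y) else 2.5
  if (family == "gaussian" && !is.null(fixed_sigma))
    jd$sigma_fixed <- fixed_sigma

  monitors <- c("alpha", "beta")
  if (use_re) monitors <- c(monitors, "sd_u", "sd_v")
  if (family == "gaussian" && is.null(fixed_sigma))
    monitors <- c(monitors, "sigma")
  if (family == "negative_binomial") monitors <- c(monitors, "r")

  inits <- lapply(seq_len(chains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (as.integer(seed) * 101L + ch * 7919L) %% 2147483629L))
  mstr <- jags_model_string(family, use_re, fixed_sigma)
  jm <- rjags::jags.model(textConnection(mstr), data = jd, inits = inits,
                          n.chains = chains, n.adapt = 1000, quiet = TRUE)
  update(jm, burn_in, progress.bar = "none")
  draws <- rjags::coda.samples(jm, monitors, n.iter = iter - burn_in,
                               progress.bar = "none")

  dm <- lapply(draws, as.matrix)
  par_names <- colnames(dm[[1]])
  rh <- vapply(par_names, function(p)
    rhat(do.call(cbind, lapply(dm, function(m) m[, p]))), numeric(1))
  beta_draws <- unlist(lapply(dm, function(m) m[, "beta"]))
  alpha_draws <- unlist(lapply(dm, function(m) m[, "alpha"]))
  alp <- (1 - ci_level) / 2
  cri <- unname(stats::quantile(beta_draws, c(alp, 1 - alp)))
  pd <- probability_of_direction(beta_draws)
  converged <- all(rh < 1.1)
  if (!converged)
    warning(sprintf("non-convergence: max R-hat %.3f (%s); flagged",
                    max(rh), par_names[which.max(rh)]))
  ess <- tryCatch(as.numeric(coda::effectiveSize(draws)[ "beta"]),
                  error = function(e) NA_real_)
  se <- stats::sd(beta_draws)
  summ <- list(
    beta = mean(beta_draws), se = se,
    cri_low = cri[1], cri_high = cri[2], pd = pd,
    rhat = rh, rhat_max = max(rh), converged = converged,
    effect_class = classify_effect(cri[1], cri[2], pd, converged),
    alpha = mean(alpha_draws),
    ess_beta = ess, mcse_beta = se / sqrt(max(ess, 1)))
  structure(list(response = response, label = label, family = family,
                 draws = draws, summary = summ,
                 standardization = std[c("mean", "sd")],
                 data = data.frame(x = data$gamefarm_fraction, y = y),
                 n = length(y), n_individuals = nlevels(ind),
                 n_years = nlevels(yr), n_dropped = n_dropped,
                 random_effects = use_re, ci_level = ci_level,
                 chains = chains, iter = iter, burn_in = burn_in,
                 seed = seed),
            class = "ancestry_fit")
}

#' @export
print.ancestry_fit <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<ancestry_fit> %s (%s), n = %d tracks\n",
              x$label, x$family, x$n))
  cat(sprintf("  beta = %.3f (SE %.3f), %d%% CrI [%.3f, %.3f], pd = %.2f%%\n",
              s$beta, s$se, round(100 * x$ci_level), s$cri_low, s$cri_high,
              s$pd))
  cat(sprintf("  max R-hat %.3f (%s), effect: %s\n", s$rhat_max,
              if (s$converged) "converged" else "NOT converged",
              s$effect_class))
  invisible(x)
}

#' @export
coef.ancestry_fit <- function(object, ...) {
  c(alpha = object$summary$alpha, beta = object$summary$beta)
}

#' @export
summary.ancestry_fit <- function(object, ...) {
  s <- object$summary
  out <- data.frame(model = object$label, family = object$family,
                    n = object$n, beta = s$beta, se = s$se,
                    cri_low = s$cri_low, cri_high = s$cri_high, pd = s$pd,
                    rhat_max = s$rhat_max, effect_class = s$effect_class,
                    stringsAsFactors = FALSE)
  class(out) <- c("summary.ancestry_fit", "data.frame")
  out
}

link_inv <- function(family) {
  if (family == "gaussian") identity else exp
}

#' Posterior marginal-effect predictions
#'
#' Population-level predicted response over a grid of game-farm ancestry
#' fractions, with an equal-tailed credible band.
#'
#' @param object an `ancestry_fit`.
#' @param newdata numeric vector of ancestry fractions (default: a grid over
#'   the observed range).
#' @param ... unused.
#' @return data frame: `gamefarm_fraction`, `fit`, `lower`, `upper`.
#' @export
predict.ancestry_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    newdata <- seq(min(object$data$x), max(object$data$x), length.out = 50)
  z <- (newdata - object$standardization$mean) /
    (2 * object$standardization$sd)
  dm <- do.call(rbind, lapply(object$draws, as.matrix))
  inv <- link_inv(object$family)
  alp <- (1 - object$ci_level) / 2
  eta <- outer(dm[, "alpha"], rep(1, length(z))) +
    outer(dm[, "beta"], z)
  mu <- inv(eta)
  data.frame(gamefarm_fraction = newdata,
             fit = colMeans(mu),
             lower = apply(mu, 2, stats::quantile, probs = alp),
             upper = apply(mu, 2, stats::quantile, probs = 1 - alp))
}

#' @export
residuals.ancestry_fit <- function(object, ...) {
  inv <- link_inv(object$family)
  z <- (object$data$x - object$standardization$mean) /
    (2 * object$standardization$sd)
  object$data$y - inv(object$summary$alpha + object$summary$beta * z)
}

#' Plot the marginal ancestry effect
#'
#' Mean predicted response with the credible band over observed ancestry,
#' raw tracks as points.
#'
#' @param x an `ancestry_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ancestry_fit <- function(x, ...) {
  pr <- predict(x)
  pct <- 100 * pr$gamefarm_fraction
  graphics::plot(100 * x$data$x, x$data$y, pch = 16,
                 col = grDevices::grey(0.4, 0.5),
                 xlab = "game-farm ancestry (%)", ylab = x$label, ...)
  graphics::polygon(c(pct, rev(pct)), c(pr$lower, rev(pr$upper)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(pct, pr$fit, lwd = 2, col = "steelblue4")
  invisible(x)
}

#' Default response/family assignment for the eight models
#'
#' @return data frame with columns `response`, `label`, `family`.
#' @export
default_model_specs <- function() {
  data.frame(
    response = c("departure_doy", "arrival_doy", "arrival_lat",
                 "n_stopovers", "stopover_duration_h",
                 "distance_to_urban_km", "migration_distance_km",
                 "migration_duration_days"),
    label = c("Departure date", "Arrival date", "Arrival latitude",
              "Number of stopovers", "Stopover duration",
              "Distance to urban", "Migration total", "Migration duration"),
    family = c("gaussian", "gaussian", "gaussian", "poisson",
               "negative_binomial", "gaussian", "gaussian", "gaussian"),
    stringsAsFactors = FALSE)
}

#' Fit the eight univariate ancestry models
#'
#' One [fit_ancestry_model()] per response in `specs`, with per-model seeds
#' derived from `seed`.
#'
#' @param phenology phenology data frame (one row per complete track).
#' @param specs data frame like [default_model_specs()].
#' @param chains,iter,burn_in,ci_level MCMC settings shared by all models.
#' @param seed integer master seed.
#' @return object of class `ancestry_fit_list` (a list of fits plus a
#'   summary table).
#' @export
fit_ancestry_models <- function(phenology, specs = default_model_specs(),
                                chains = 4, iter = 10000, burn_in = 4000,
                                ci_level = 0.90, seed = 1L) {
  fits <- list()
  for (i in seq_len(nrow(specs))) {
    resp <- specs$response[i]
    if (!resp %in% names(phenology) ||
        all(!is.finite(phenology[[resp]]))) {
      message("skipping ", resp, ": no data")
      next
    }
    fits[[resp]] <- fit_ancestry_model(
      phenology, resp, family = specs$family[i], chains = chains,
      iter = iter, burn_in = burn_in, ci_level = ci_level,
      seed = as.integer(seed) + i, label = specs$label[i])
  }
  structure(list(fits = fits,
                 table = do.call(rbind, lapply(fits, summary))),
            class = "ancestry_fit_list")
}

#' @export
print.ancestry_fit_list <- function(x, ...) {
  cat(sprintf("<ancestry_fit_list> %d model(s)\n", length(x$fits)))
  tb <- x$table
  tb[, sapply(tb, is.numeric)] <- round(tb[, sapply(tb, is.numeric)], 3)
  print(tb, row.names = FALSE)
  invisible(x)
}

#' @export
summary.ancestry_fit_list <- function(object, ...) object$table
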