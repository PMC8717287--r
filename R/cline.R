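#' Equilibrium geographic cline model
#'
#' The central cline is the sigmoid
#' \deqn{s(x) = (1 + \tanh(2 (x - c) / w)) / 2,}
#' rescaled to \eqn{p(x) = p_{min} + (p_{max} - p_{min}) s(x)}.  Three model
#' classes are distinguished: model I fixes `pmin`/`pmax` at the observed
#' data extremes, model II frees them, and model III additionally fits two
#' exponential tails.  The left tail replaces \eqn{s} for
#' \eqn{x < x_L = c - \delta_L} by
#' \deqn{s(x) = s(x_L) \exp\{\tau_L s'(x_L) (x - x_L) / s(x_L)\}}
#' and symmetrically on the right for \eqn{x > x_R = c + \delta_R}; the tails
#' are value-continuous everywhere and slope-continuous when \eqn{\tau = 1}.
#'
#' @param model_class `"I_fixed_none"`, `"II_free_none"` or `"III_free_both"`.
#' @param c cline centre, km (location of steepest change).
#' @param w cline width parameter, km (> 0); the inverse-of-maximum-slope
#'   width is `w / (pmax - pmin)`.
#' @param pmin,pmax trait bounds in \[0, 1\].
#' @param deltaL,deltaR tail offsets from the centre, km (>= 0).
#' @param tauL,tauR tail slope scales in \[0, 1\].
#' @return an object of class `cline_model`.
#' @export
cline_model <- function(model_class = c("I_fixed_none", "II_free_none",
                                        "III_free_both"),
                        c, w, pmin = 0, pmax = 1,
                        deltaL = 0, tauL = 0, deltaR = 0, tauR = 0) {
  model_class <- match.arg(model_class)
  if (!is.finite(w) || w <= 0) stop("cline width w must be > 0")
  if (pmin > pmax) stop("pmin must not exceed pmax")
  if (pmin < 0 || pmax > 1) stop("pmin/pmax must lie in [0, 1]")
  if (deltaL < 0 || deltaR < 0) stop("tail offsets must be >= 0")
  if (tauL < 0 || tauL > 1 || tauR < 0 || tauR > 1) {
    stop("tail slope scales tau must lie in [0, 1]")
  }
  structure(
    list(model_class = model_class, c = c, w = w, pmin = pmin, pmax = pmax,
         deltaL = deltaL, tauL = tauL, deltaR = deltaR, tauR = tauR),
    class = "cline_model"
  )
}

# central sigmoid and its derivative
.cline_s <- function(x, c, w) (1 + tanh(2 * (x - c) / w)) / 2
.cline_sprime <- function(x, c, w) (1 - tanh(2 * (x - c) / w)^2) / w

#' Evaluate a cline model
#'
#' @param model a [cline_model()].
#' @param x positions along the transect, km.
#' @return trait values `p(x)`, monotone non-decreasing in `x`.
#' @export
cline_value <- function(model, x) {
  s <- .cline_s(x, model$c, model$w)
  if (model$model_class == "III_free_both") {
    if (model$tauL > 0 || model$deltaL > 0) {
      xL <- model$c - model$deltaL
      sL <- .cline_s(xL, model$c, model$w)
      spL <- .cline_sprime(xL, model$c, model$w)
      left <- x < xL
      # when the sigmoid has already saturated at the junction the tail is
      # numerically flat; avoid 0/0 in the exponent
      s[left] <- if (sL <= 1e-12) sL else
        sL * exp(model$tauL * spL * (x[left] - xL) / sL)
    }
    if (model$tauR > 0 || model$deltaR > 0) {
      xR <- model$c + model$deltaR
      sR <- .cline_s(xR, model$c, model$w)
      spR <- .cline_sprime(xR, model$c, model$w)
      right <- x > xR
      s[right] <- if (1 - sR <= 1e-12) sR else
        1 - (1 - sR) * exp(-model$tauR * spR * (x[right] - xR) / (1 - sR))
    }
  }
  model$pmin + (model$pmax - model$pmin) * s
}

#' Cline log-likelihood at individual localities
#'
#' Each specimen is its own sampling locality, so the likelihood is a
#' product over individuals.  Binary traits (mtDNA haplogroup, colour
#' phenotype) use a Bernoulli likelihood with the fitted probability clamped
#' to \[1e-9, 1 - 1e-9\]; continuous traits (ancestry proportions) use a
#' Gaussian likelihood with free residual standard deviation `sigma`.
#'
#' @param model a [cline_model()].
#' @param x,y positions (km) and trait values; `y` in \{0, 1\} for
#'   `"bernoulli"`, in \[0, 1\] for `"gaussian"`.
#' @param likelihood `"bernoulli"` or `"gaussian"`.
#' @param sigma residual SD for the Gaussian likelihood.
#' @return total log-likelihood.
#' @export
cline_log_likelihood <- function(model, x, y,
                                 likelihood = c("bernoulli", "gaussian"),
                                 sigma = NULL) {
  likelihood <- match.arg(likelihood)
  if (length(x) == 0 || length(x) != length(y)) {
    stop("x and y must be non-empty and of equal length")
  }
  p <- cline_value(model, x)
  if (likelihood == "bernoulli") {
    if (!all(y %in% c(0, 1))) stop("bernoulli likelihood needs y in {0, 1}")
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    sum(y * log(p) + (1 - y) * log(1 - p))
  } else {
    if (is.null(sigma) || sigma <= 0) stop("gaussian likelihood needs sigma > 0")
    sum(stats::dnorm(y, mean = p, sd = sigma, log = TRUE))
  }
}

#' Small-sample corrected Akaike information criterion
#'
#' @param logL_max maximised log-likelihood.
#' @param k number of free parameters.
#' @param n number of localities (individuals, here).
#' @return `2k - 2 logL + 2k(k+1)/(n-k-1)`.
#' @export
aicc <- function(logL_max, k, n) {
  if (n <= k + 1) stop("AICc requires n > k + 1")
  2 * k - 2 * logL_max + 2 * k * (k + 1) / (n - k - 1)
}

# free parameter names for a model class / likelihood combination
.cline_par_names <- function(model_class, likelihood) {
  pars <- c("c", "w")
  if (model_class != "I_fixed_none") pars <- c(pars, "pmin", "pmax")
  if (model_class == "III_free_both") {
    pars <- c(pars, "deltaL", "tauL", "deltaR", "tauR")
  }
  if (likelihood == "gaussian") pars <- c(pars, "sigma")
  pars
}

.cline_prior_bounds <- function(pars, x_range) {
  span <- diff(x_range)
  lower <- c(c = x_range[1], w = 1e-6, pmin = 0, pmax = 0,
             deltaL = 0, tauL = 0, deltaR = 0, tauR = 0, sigma = 1e-6)
  upper <- c(c = x_range[2], w = 3 * span, pmin = 1, pmax = 1,
             deltaL = span, tauL = 1, deltaR = span, tauR = 1, sigma = 1)
  list(lower = lower[pars], upper = upper[pars])
}

.cline_from_theta <- function(theta, model_class, fixed_bounds) {
  pmin <- if ("pmin" %in% names(theta)) theta[["pmin"]] else fixed_bounds[1]
  pmax <- if ("pmax" %in% names(theta)) theta[["pmax"]] else fixed_bounds[2]
  cline_model(
    model_class, c = theta[["c"]], w = theta[["w"]],
    pmin = pmin, pmax = pmax,
    deltaL = if ("deltaL" %in% names(theta)) theta[["deltaL"]] else 0,
    tauL   = if ("tauL" %in% names(theta)) theta[["tauL"]] else 0,
    deltaR = if ("deltaR" %in% names(theta)) theta[["deltaR"]] else 0,
    tauR   = if ("tauR" %in% names(theta)) theta[["tauR"]] else 0
  )
}

#' Fit an equilibrium cline by Metropolis-Hastings MCMC
#'
#' Uniform priors: centre over the data range; width in (0, 3 x range\];
#' `pmin`, `pmax` in \[0, 1\] with `pmin < pmax`; tail offsets in
#' \[0, range\]; tail scales in \[0, 1\]; `sigma` in (0, 1\].  Sampling is
#' componentwise Gaussian random walk; per-parameter proposal scales are
#' adapted during burn-in towards an acceptance rate of 0.2-0.4 and then
#' frozen.  Results are reproducible for a given `seed`.
#'
#' @param x,y data: transect positions (km) and trait values.
#' @param model_class cline model class, see [cline_model()].
#' @param likelihood `"bernoulli"` or `"gaussian"`.
#' @param iterations total MCMC sweeps.
#' @param burnin_fraction fraction of sweeps discarded as burn-in.
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param seed RNG seed.
#' @return a `cline_fit` with elements `model` (maximum-posterior sample),
#'   `samples` (thinned posterior draws), `logL_max`, `k`, `n`, `aicc`,
#'   `center_ci` (95% equal-tailed credible interval), `center_support`
#'   (2-log-likelihood support region), `width_param`,
#'   `width_inv_max_slope`, `likelihood`, `sigma`, `seed`.
#' @export
fit_cline <- function(x, y,
                      model_class = c("I_fixed_none", "II_free_none",
                                      "III_free_both"),
                      likelihood = c("bernoulli", "gaussian"),
                      iterations = 1e5, burnin_fraction = 0.1, thin = 10,
                      seed = 1) {
  model_class <- match.arg(model_class)
  likelihood <- match.arg(likelihood)
  if (length(x) < 10) stop("need at least 10 data points")
  x_range <- range(x)
  if (diff(x_range) <= 0) stop("data must span > 0 km of transect")
  fixed_bounds <- range(y)

  pars <- .cline_par_names(model_class, likelihood)
  pr <- .cline_prior_bounds(pars, x_range)

  theta_ok <- function(theta) {
    if (any(theta < pr$lower | theta > pr$upper)) return(FALSE)
    if (all(c("pmin", "pmax") %in% pars) &&
        theta[["pmin"]] >= theta[["pmax"]]) return(FALSE)
    TRUE
  }
  log_lik <- function(theta) {
    m <- .cline_from_theta(theta, model_class, fixed_bounds)
    sig <- if ("sigma" %in% pars) theta[["sigma"]] else NULL
    cline_log_likelihood(m, x, y, likelihood, sigma = sig)
  }

  set.seed(seed)
  theta <- NULL
  for (try in seq_len(100)) {
    cand <- stats::runif(length(pars), pr$lower, pr$upper)
    names(cand) <- pars
    if (!theta_ok(cand)) next
    ll <- log_lik(cand)
    if (is.finite(ll)) { theta <- cand; break }
  }
  if (is.null(theta)) stop("could not initialise MCMC with finite likelihood")

  n_burn <- floor(iterations * burnin_fraction)
  scales <- 0.1 * (pr$upper - pr$lower)
  acc <- rej <- stats::setNames(numeric(length(pars)), pars)
  adapt_every <- 50

  n_keep <- floor((iterations - n_burn) / thin)
  samples <- matrix(NA_real_, n_keep, length(pars),
                    dimnames = list(NULL, pars))
  sample_ll <- numeric(n_keep)
  keep_i <- 0
  ll_cur <- ll
  best_ll <- -Inf
  best_post_theta <- theta
  best_post_ll <- -Inf

  for (it in seq_len(iterations)) {
    for (j in seq_along(pars)) {
      prop <- theta
      prop[j] <- theta[j] + stats::rnorm(1, 0, scales[j])
      if (!theta_ok(prop)) { rej[j] <- rej[j] + 1; next }
      ll_prop <- log_lik(prop)
      if (is.finite(ll_prop) &&
          log(stats::runif(1)) < ll_prop - ll_cur) {
        theta <- prop; ll_cur <- ll_prop; acc[j] <- acc[j] + 1
      } else {
        rej[j] <- rej[j] + 1
      }
    }
    if (it <= n_burn && it %% adapt_every == 0) {
      rate <- acc / pmax(acc + rej, 1)
      scales[rate > 0.4] <- scales[rate > 0.4] * 1.5
      scales[rate < 0.2] <- scales[rate < 0.2] / 1.5
      acc[] <- 0; rej[] <- 0
    }
    if (it > n_burn) {
      if (ll_cur > best_ll) best_ll <- ll_cur
      # flat priors: posterior density is proportional to the likelihood
      if (ll_cur > best_post_ll) { best_post_ll <- ll_cur; best_post_theta <- theta }
      if ((it - n_burn) %% thin == 0 && keep_i < n_keep) {
        keep_i <- keep_i + 1
        samples[keep_i, ] <- theta
        sample_ll[keep_i] <- ll_cur
      }
    }
  }
  samples <- samples[seq_len(keep_i), , drop = FALSE]
  sample_ll <- sample_ll[seq_len(keep_i)]

  model <- .cline_from_theta(best_post_theta, model_class, fixed_bounds)
  k <- length(pars)
  n <- length(x)
  ci <- stats::quantile(samples[, "c"], c(0.025, 0.975), names = FALSE)
  in_support <- sample_ll >= best_ll - 2
  support <- range(samples[in_support, "c"])
  p_span <- model$pmax - model$pmin
  structure(
    list(model = model, samples = samples, sample_logL = sample_ll,
         logL_max = best_ll, k = k, n = n,
         aicc = aicc(best_ll, k, n),
         center_ci = ci, center_support = support,
         width_param = model$w,
         width_inv_max_slope = if (p_span > 0) model$w / p_span else NA_real_,
         likelihood = likelihood,
         sigma = if ("sigma" %in% pars) best_post_theta[["sigma"]] else NULL,
         seed = seed, data = list(x = x, y = y)),
    class = "cline_fit"
  )
}

#' @export
print.cline_fit <- function(x, ...) {
  cat(sprintf(
    "cline fit (%s, %s): center %.1f km [95%% CI %.1f-%.1f], width %.1f km, AICc %.2f\n",
    x$model$model_class, x$likelihood, x$model$c,
    x$center_ci[1], x$center_ci[2], x$width_param, x$aicc))
  invisible(x)
}

#' Select among cline model fits by AICc
#'
#' @param fits list of `cline_fit` objects fitted to identical data.
#' @return list with `best` (minimum-AICc fit; ties go to the fit with
#'   fewer parameters) and `table` (model class, k, logL, AICc, delta AICc).
#' @export
select_model <- function(fits) {
  if (length(fits) == 0) stop("no fits supplied")
  d0 <- fits[[1]]$data
  for (f in fits) {
    if (!identical(f$data$x, d0$x) || !identical(f$data$y, d0$y)) {
      stop("all fits must be on identical data")
    }
  }
  tab <- data.frame(
    model_class = vapply(fits, function(f) f$model$model_class, ""),
    k = vapply(fits, function(f) f$k, 0),
    logL_max = vapply(fits, function(f) f$logL_max, 0),
    aicc = vapply(fits, function(f) f$aicc, 0)
  )
  tab$delta_aicc <- tab$aicc - min(tab$aicc)
  best_idx <- order(tab$aicc, tab$k)[1]
  list(best = fits[[best_idx]], table = tab)
}

#' Compare two fitted clines
#'
#' @param fitA,fitB `cline_fit` objects on the same transect coordinates.
#' @return list with `center_shift_km` (centre of A minus centre of B at the
#'   point estimates), `width_diff_km`, and `shift_posterior`
#'   (posterior draws of the shift from paired independent samples, with a
#'   95% interval).
#' @export
compare_clines <- function(fitA, fitB) {
  shift <- fitA$model$c - fitB$model$c
  width_diff <- fitA$model$w - fitB$model$w
  n <- min(nrow(fitA$samples), nrow(fitB$samples))
  draws <- fitA$samples[seq_len(n), "c"] - fitB$samples[seq_len(n), "c"]
  list(center_shift_km = shift,
       width_diff_km = width_diff,
       shift_posterior = draws,
       shift_ci = stats::quantile(draws, c(0.025, 0.975), names = FALSE))
}
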