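#' State-space parameters of the latent log-branching-rate model
#'
#' The latent state follows an AR(1) Gaussian model
#' x_k = rho * x_{k-1} + eps_k, eps_k ~ N(0, sigma_eps2), and drives the
#' per-bin event rate lambda_k = exp(mu + beta * x_k) (events per bin;
#' divide by delta for events per um).
#'
#' @param rho AR(1) coefficient, |rho| <= 1.
#' @param mu baseline log-rate (log events per bin).
#' @param beta state gain; the default parameterization fixes beta = 1
#'   since (beta, x) are jointly identifiable only up to scale.
#' @param sigma_eps2 state noise variance, > 0.
#' @return object of class `ss_params`.
#' @export
ss_params <- function(rho, mu, beta = 1, sigma_eps2) {
  if (sigma_eps2 <= 0) stop("sigma_eps2 must be positive")
  if (abs(rho) > 1) stop("|rho| must be <= 1")
  structure(list(rho = rho, mu = mu, beta = beta, sigma_eps2 = sigma_eps2),
            class = "ss_params")
}

#' @export
print.ss_params <- function(x, ...) {
  cat(sprintf("ss_params: rho=%.4f mu=%.4f beta=%.4f sigma_eps2=%.5f\n",
              x$rho, x$mu, x$beta, x$sigma_eps2))
  invisible(x)
}

stationary_var <- function(params) {
  if (abs(params$rho) < 1) params$sigma_eps2 / (1 - params$rho^2) else params$sigma_eps2
}

# solve the implicit filter update for x_{k|k}:
#   x = xp + sp * beta * (c - n * exp(mu + beta x) * delta)
# damped fixed point from xp, falling back to root finding on the
# posterior score if it fails to settle
solve_update <- function(xp, sp, c_k, n_k, params, delta,
                         max_iter = 100L, tol = 1e-10) {
  b <- params$beta; mu <- params$mu
  g <- function(x) xp + sp * b * (c_k - n_k * exp(mu + b * x) * delta)
  x <- xp
  damp <- 1
  for (i in seq_len(max_iter)) {
    xn <- x + damp * (g(x) - x)
    if (!is.finite(xn)) break
    if (abs(xn - x) < tol) return(xn)
    if (i %% 20L == 0L) damp <- damp / 2   # oscillation guard
    x <- xn
  }
  # fallback: Newton with step-halving on the strictly concave
  # log-posterior; its unique maximum is the fixed point
  logpost <- function(x) -(x - xp)^2 / (2 * sp) + c_k * b * x -
    n_k * exp(mu + b * x) * delta
  x <- xp
  for (i in seq_len(200L)) {
    e <- n_k * exp(mu + b * x) * delta
    g1 <- -(x - xp) / sp + b * c_k - b * e
    g2 <- -1 / sp - b^2 * e
    step <- -g1 / g2
    f0 <- logpost(x)
    while (!is.finite(logpost(x + step)) || logpost(x + step) < f0 - 1e-12) {
      step <- step / 2
      if (abs(step) < 1e-15) break
    }
    x <- x + step
    if (abs(step) < 1e-12) return(x)
  }
  stop("filter update failed to converge (counts = ", c_k, ")")
}

#' Forward point-process filter
#'
#' One-step prediction and recursive nonlinear update of the latent state
#' given pooled binary event sequences. Sequences that have already
#' terminated (absolute axis) drop out of the update at later bins.
#'
#' @param pp a `pp_set`.
#' @param params an `ss_params`.
#' @param x0 initial state mean (default 0).
#' @param s0 initial state variance; default is the stationary AR(1)
#'   variance sigma_eps2 / (1 - rho^2) when |rho| < 1, else sigma_eps2.
#' @return object of class `pp_filter` with per-bin one-step predictions
#'   (`x_pred`, `var_pred`) and filtered estimates (`x_filt`, `var_filt`),
#'   plus the per-bin event counts and active-sequence counts used.
#' @export
filter_forward <- function(pp, params, x0 = 0, s0 = NULL) {
  if (is.null(s0)) s0 <- stationary_var(params)
  suff <- pp_sufficient(pp)
  K <- pp$K
  xp <- vp <- xf <- vf <- numeric(K)
  x <- x0; s <- s0
  for (k in seq_len(K)) {
    xp[k] <- params$rho * x
    vp[k] <- params$rho^2 * s + params$sigma_eps2
    xf[k] <- solve_update(xp[k], vp[k], suff$counts[k], suff$n_active[k],
                          params, pp$delta)
    vf[k] <- 1 / (1 / vp[k] +
                    suff$n_active[k] * params$beta^2 *
                    exp(params$mu + params$beta * xf[k]) * pp$delta)
    x <- xf[k]; s <- vf[k]
  }
  structure(list(x_pred = xp, var_pred = vp, x_filt = xf, var_filt = vf,
                 counts = suff$counts, n_active = suff$n_active,
                 x0 = x0, s0 = s0, params = params, delta = pp$delta, K = K,
                 normalized = isTRUE(pp$normalized)),
            class = "pp_filter")
}

#' Fixed-interval smoother
#'
#' Backward recursion combining the forward filter with future data:
#' x_{k|K} = x_{k|k} + A_k (x_{k+1|K} - x_{k+1|k}) with smoother gain
#' A_k = rho * var_{k|k} / var_{k+1|k}. The reported rate is the expected
#' number of events per bin, lambda_k = exp(mu + beta * x_{k|K}) * delta;
#' divide by delta for the intensity per unit of the pathlength axis.
#'
#' @param fs a `pp_filter` from [filter_forward()].
#' @param params an `ss_params`; defaults to the parameters stored in `fs`.
#' @return object of class `rate_estimate` with `x_smooth`, `var_smooth`,
#'   smoother gains `A`, and `lambda` (events per bin).
#' @export
smooth_rate <- function(fs, params = fs$params) {
  K <- fs$K
  xs <- fs$x_filt; vs <- fs$var_filt
  A <- numeric(K)
  if (K > 1L) {
    for (k in (K - 1L):1L) {
      A[k] <- params$rho * fs$var_filt[k] / fs$var_pred[k + 1L]
      xs[k] <- fs$x_filt[k] + A[k] * (xs[k + 1L] - fs$x_pred[k + 1L])
      vs[k] <- fs$var_filt[k] + A[k]^2 * (vs[k + 1L] - fs$var_pred[k + 1L])
    }
  }
  structure(list(x_smooth = xs, var_smooth = vs, A = A,
                 lambda = exp(params$mu + params$beta * xs) * fs$delta,
                 params = params, delta = fs$delta, K = K,
                 normalized = isTRUE(fs$normalized), filter = fs),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("rate_estimate: K=%d bins, lambda in [%.4g, %.4g] events/bin\n",
              x$K, min(x$lambda), max(x$lambda)))
  print(x$params)
  invisible(x)
}

#' Tidy per-bin table of a rate estimate
#' @param re a `rate_estimate`
#' @return data.frame with bin, pathlength (bin upper edge), smoothed state,
#'   smoothed variance and rate per bin
#' @export
rate_table <- function(re) {
  data.frame(bin = seq_len(re$K),
             pathlength = seq_len(re$K) * re$delta,
             x_smooth = re$x_smooth,
             var_smooth = re$var_smooth,
             lambda = re$lambda)
}

# Gauss-Hermite nodes/weights by Golub-Welsch on the Jacobi matrix
gauss_hermite <- function(n) {
  off <- sqrt(seq_len(n - 1) / 2)
  J <- diag(0, n)
  J[cbind(1:(n - 1), 2:n)] <- off
  J[cbind(2:n, 1:(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# observed-data log-likelihood, integrating each bin's Poisson-Bernoulli
# likelihood over the one-step predictive Gaussian (Gauss-Hermite)
pp_loglik <- function(pp, params, x0 = 0, s0 = NULL, gh = gauss_hermite(30L)) {
  fs <- filter_forward(pp, params, x0, s0)
  ll <- 0
  for (k in seq_len(pp$K)) {
    xj <- fs$x_pred[k] + sqrt(2 * fs$var_pred[k]) * gh$nodes
    eta <- params$mu + params$beta * xj
    lf <- fs$counts[k] * eta - fs$n_active[k] * exp(eta) * pp$delta
    m <- max(lf)
    ll <- ll + m + log(sum(gh$weights / sqrt(pi) * exp(lf - m)))
  }
  ll
}

#' Fit the state-space model by expectation-maximization
#'
#' Alternates the forward filter and fixed-interval smoother (E-step,
#' Gaussian approximation to the smoothed posterior) with closed-form
#' updates of rho and sigma_eps2 from the smoothed second moments and a
#' closed-form/Newton update of mu (M-step). beta is fixed at its initial
#' value by default because (beta, x) are only identified up to scale; set
#' `fit_beta = TRUE` for full 4-parameter estimation.
#'
#' @param pp a `pp_set` with at least one event.
#' @param init optional `ss_params` initializer. Default: rho = 0.9,
#'   mu = log(N_total / (R * K)) - log(delta), beta = 1, sigma_eps2 = 0.1.
#' @param tol convergence tolerance on the largest absolute parameter
#'   change (default 1e-5).
#' @param max_iter iteration cap (default 500); reaching it returns with
#'   `converged = FALSE` and a warning.
#' @param fit_beta also estimate beta (default FALSE).
#' @param ll_tol log-likelihood plateau tolerance: EM also stops once an
#'   iteration improves the observed-data log-likelihood by less than
#'   this. Because the E-step uses a Gaussian approximation an update can
#'   in principle decrease the likelihood slightly; such a step is rolled
#'   back and EM stops, so the reported trace is non-decreasing.
#' @return list with `params` (fitted `ss_params`), `rate` (the final
#'   smoothed `rate_estimate`), `loglik` (per-iteration observed-data
#'   log-likelihood), `converged`, `iterations`.
#' @export
em_fit <- function(pp, init = NULL, tol = 1e-5, max_iter = 500L,
                   fit_beta = FALSE, ll_tol = 1e-6) {
  if (pp$N_total < 1) stop("point-process set holds no events")
  if (is.null(init)) {
    init <- ss_params(rho = 0.9, mu = log(pp$N_total / (pp$R * pp$K)),
                      beta = 1, sigma_eps2 = 0.1)
  }
  params <- init
  gh <- gauss_hermite(30L)
  suff <- pp_sufficient(pp)
  K <- pp$K
  ll_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  # the initial state is estimated alongside the parameters, with a fixed
  # prior variance of sigma_eps2; tying the prior to the stationary
  # variance couples it to rho and breaks the EM ascent near |rho| = 1
  x0 <- 0

  repeat {
    iter <- iter + 1L
    # ---- E-step
    s0 <- params$sigma_eps2
    fs <- filter_forward(pp, params, x0, s0)
    sm <- smooth_rate(fs, params)
    ll <- pp_loglik(pp, params, x0, s0, gh)
    if (!is.finite(ll)) stop("non-finite log-likelihood at EM iteration ", iter)
    if (iter > 1L && ll < ll_trace[iter - 1L]) {
      # approximate E-step produced a non-ascending update: roll back
      params <- prev_params; x0 <- prev_x0
      converged <- TRUE
      break
    }
    ll_trace <- c(ll_trace, ll)
    if (iter > 1L && ll - ll_trace[iter - 1L] < ll_tol) {
      converged <- TRUE
      break
    }
    prev_params <- params; prev_x0 <- x0

    xs <- sm$x_smooth; vs <- sm$var_smooth; A <- sm$A
    # smooth back to the initial state
    A0 <- params$rho * s0 / fs$var_pred[1]
    x0s <- x0 + A0 * (xs[1] - fs$x_pred[1])
    v0s <- s0 + A0^2 * (vs[1] - fs$var_pred[1])
    # second moments E[x_k^2] and cross moments E[x_k x_{k-1}]
    W <- vs + xs^2
    Wprev <- c(v0s + x0s^2, W[-K])
    cross <- numeric(K)
    cross[1] <- A0 * vs[1] + xs[1] * x0s
    if (K > 1L) {
      for (k in 2:K) cross[k] <- A[k - 1L] * vs[k] + xs[k] * xs[k - 1L]
    }

    # ---- M-step
    rho_new <- sum(cross) / sum(Wprev)
    rho_new <- max(-0.9999, min(0.9999, rho_new))
    sig_new <- max(1e-10,
                   (v0s + sum(W - 2 * rho_new * cross + rho_new^2 * Wprev)) /
                     (K + 1))
    x0_new <- x0s
    if (fit_beta) {
      obj <- function(p) {
        eta <- p[1] + p[2] * xs
        -(sum(suff$counts * eta) -
            pp$delta * sum(suff$n_active * exp(eta + p[2]^2 * vs / 2)))
      }
      opt <- stats::optim(c(params$mu, params$beta), obj, method = "BFGS")
      mu_new <- opt$par[1]; beta_new <- opt$par[2]
    } else {
      beta_new <- params$beta
      mu_new <- log(sum(suff$counts) /
                      (pp$delta * sum(suff$n_active *
                                        exp(beta_new * xs + beta_new^2 * vs / 2))))
      if (!is.finite(mu_new)) stop("non-finite mu update in EM M-step")
    }

    dpar <- max(abs(c(rho_new - params$rho, mu_new - params$mu,
                      beta_new - params$beta, sig_new - params$sigma_eps2,
                      x0_new - x0)))
    params <- ss_params(rho_new, mu_new, beta_new, sig_new)
    x0 <- x0_new
    if (is.infinite(tol) || dpar < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged) warning("EM reached max_iter = ", max_iter, " without converging")

  fs <- filter_forward(pp, params, x0, params$sigma_eps2)
  rate <- smooth_rate(fs, params)
  list(params = params, rate = rate, loglik = ll_trace, x0 = x0,
       converged = converged, iterations = iter)
}

#' Estimate the branching rate of a set of morphologies
#'
#' Convenience composition: encode all terminal paths of all trees into one
#' pooled point-process set, then fit the state-space model by EM. The
#' returned rate is the population branching-rate estimate on the chosen
#' pathlength axis.
#'
#' @param trees a `morph_tree` or list of them.
#' @param delta,normalize,bins passed to [encode_point_processes()].
#' @param ... passed to [em_fit()].
#' @return the list returned by [em_fit()], plus the encoded `pp` set.
#' @export
estimate_branching_rate <- function(trees, delta = NULL, normalize = TRUE,
                                    bins = 100L, ...) {
  pp <- encode_point_processes(trees, delta = delta, normalize = normalize,
                               bins = bins)
  fit <- em_fit(pp, ...)
  fit$pp <- pp
  fit
}
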