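#' Fit a two-component 1D Gaussian mixture by EM
#'
#' The automatic-threshold machinery: vertices are clustered into two
#' groups by a univariate two-component Gaussian mixture fitted by
#' expectation-maximization, and the threshold is the equiprobable decision
#' boundary between the components (see [decision_boundary()]).
#'
#' Initialization is a k-means++-style 2-means on the values, repeated
#' `n_restarts` times; the highest-likelihood fit is kept. Component
#' variances are floored at `1e-6` times the data variance to prevent
#' singular collapse onto duplicated values. Components are ordered by
#' ascending mean. A fit whose means are separated by less than one pooled
#' standard deviation (the standard deviation of all values pooled
#' together) is flagged `low_separation`; downstream stages decide
#' what to do with such a fit (the repair stage proceeds with a warning,
#' the second segmentation step skips removal).
#'
#' @param values numeric vector (>= 4 finite values, not all identical).
#' @param tol convergence: relative change in log-likelihood below this
#'   stops EM.
#' @param max_iter maximum EM iterations per restart.
#' @param n_restarts random restarts.
#' @param seed optional RNG seed for reproducible initialization.
#' @param var_floor override for the variance floor. For quantized data
#'   (e.g. occlusion count ratios, multiples of `1/N`) a component
#'   standard deviation below the quantization step is meaningless and EM
#'   collapses onto atoms; callers fitting such data should floor the
#'   variance at the squared half-step, `(1/(2N))^2`.
#' @return an object of class `gmm1d` with fields `weights`, `means`,
#'   `stdevs`, `log_likelihood`, `loglik_trace`, `converged`, `n_iter`,
#'   `low_separation`, and the data in `values`.
#' @export
fit_gmm2 <- function(values, tol = 1e-7, max_iter = 500L, n_restarts = 5L,
                     seed = NULL, var_floor = NULL) {
  values <- as.double(values)
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 4L) stop("need at least 4 finite values to fit a 2-component mixture")
  data_var <- var(values)
  if (data_var == 0) stop("degenerate data: all values identical")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(var_floor)) var_floor <- 1e-6 * data_var

  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- kmeanspp_init(values)
    fit <- em_gmm2(values, init, tol, max_iter, var_floor)
    if (is.null(best) || fit$log_likelihood > best$log_likelihood) best <- fit
  }
  ord <- order(best$means)
  pooled_sd <- sd(values)
  out <- structure(list(
    weights = best$weights[ord],
    means = best$means[ord],
    stdevs = best$stdevs[ord],
    log_likelihood = best$log_likelihood,
    loglik_trace = best$trace,
    converged = best$converged,
    n_iter = best$n_iter,
    low_separation = diff(best$means[ord]) < pooled_sd,
    pooled_sd = pooled_sd,
    n = n,
    values = values
  ), class = "gmm1d")
  out
}

# k-means++ seeding then a short 2-means refinement; returns responsibilities
kmeanspp_init <- function(values) {
  n <- length(values)
  c1 <- values[sample.int(n, 1L)]
  d2 <- (values - c1)^2
  if (all(d2 == 0)) {
    c2 <- c1 + sd(values)
  } else {
    c2 <- values[sample.int(n, 1L, prob = d2)]
  }
  centers <- c(c1, c2)
  for (iter in 1:10) {
    assign1 <- abs(values - centers[1]) <= abs(values - centers[2])
    if (!any(assign1) || all(assign1)) break
    new_centers <- c(mean(values[assign1]), mean(values[!assign1]))
    if (max(abs(new_centers - centers)) < 1e-12) { centers <- new_centers; break }
    centers <- new_centers
  }
  assign1 <- abs(values - centers[1]) <= abs(values - centers[2])
  # soften the hard assignment slightly so EM can move both components
  resp <- cbind(ifelse(assign1, 0.95, 0.05), ifelse(assign1, 0.05, 0.95))
  resp
}

em_gmm2 <- function(values, resp, tol, max_iter, var_floor) {
  n <- length(values)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  w <- mu <- s <- NULL
  for (iter in seq_len(max_iter)) {
    # M step
    nk <- colSums(resp)
    nk <- pmax(nk, 1e-12)
    w <- nk / n
    mu <- colSums(resp * values) / nk
    v <- colSums(resp * (outer(values, mu, `-`))^2) / nk
    s <- sqrt(pmax(v, var_floor))
    # E step + log-likelihood via log-sum-exp
    lg <- cbind(log(w[1]) + dnorm(values, mu[1], s[1], log = TRUE),
                log(w[2]) + dnorm(values, mu[2], s[2], log = TRUE))
    m <- pmax(lg[, 1], lg[, 2])
    lse <- m + log(exp(lg[, 1] - m) + exp(lg[, 2] - m))
    ll <- sum(lse)
    resp <- exp(lg - lse)
    trace <- c(trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + 1e-12)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(weights = w, means = mu, stdevs = s, log_likelihood = trace[length(trace)],
       trace = trace, converged = converged, n_iter = length(trace))
}

#' @export
print.gmm1d <- function(x, ...) {
  cat("Two-component 1D Gaussian mixture (EM), n =", x$n, "\n")
  tab <- rbind(weight = x$weights, mean = x$means, stdev = x$stdevs)
  colnames(tab) <- c("component 1", "component 2")
  print(round(tab, 5))
  cat("log-likelihood:", format(x$log_likelihood), "| iterations:", x$n_iter,
      "| converged:", x$converged, "\n")
  if (x$low_separation)
    cat("note: LOW SEPARATION (means closer than one pooled stdev)\n")
  invisible(x)
}

#' @export
summary.gmm1d <- function(object, ...) {
  thr <- tryCatch(decision_boundary(object), error = function(e) NULL)
  structure(list(model = object, threshold = thr), class = "summary.gmm1d")
}

#' @export
print.summary.gmm1d <- function(x, ...) {
  print(x$model)
  if (!is.null(x$threshold))
    cat("equiprobable decision boundary:", format(x$threshold$value), "\n")
  else
    cat("no interior equiprobable boundary\n")
  invisible(x)
}

#' @export
coef.gmm1d <- function(object, ...) {
  c(weight1 = object$weights[1], weight2 = object$weights[2],
    mean1 = object$means[1], mean2 = object$means[2],
    sd1 = object$stdevs[1], sd2 = object$stdevs[2])
}

#' @export
logLik.gmm1d <- function(object, ...) {
  structure(object$log_likelihood, df = 5L, nobs = object$n, class = "logLik")
}

#' Posterior probabilities, labels or density under a fitted mixture
#'
#' @param object a [fit_gmm2()] model.
#' @param newdata values to evaluate (defaults to the training values).
#' @param type `"posterior"` (n x 2 matrix), `"class"` (1 or 2, by
#'   posterior argmax) or `"density"` (mixture density).
#' @param ... unused.
#' @export
predict.gmm1d <- function(object, newdata = NULL,
                          type = c("posterior", "class", "density"), ...) {
  type <- match.arg(type)
  x <- if (is.null(newdata)) object$values else as.double(newdata)
  lg <- cbind(log(object$weights[1]) + dnorm(x, object$means[1],
                                             object$stdevs[1], log = TRUE),
              log(object$weights[2]) + dnorm(x, object$means[2],
                                             object$stdevs[2], log = TRUE))
  m <- pmax(lg[, 1], lg[, 2])
  lse <- m + log(exp(lg[, 1] - m) + exp(lg[, 2] - m))
  switch(type,
         posterior = exp(lg - lse),
         class = ifelse(lg[, 2] > lg[, 1], 2L, 1L),
         density = exp(lse))
}

#' @export
simulate.gmm1d <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(2L, nsim, replace = TRUE, prob = object$weights)
  rnorm(nsim, object$means[comp], object$stdevs[comp])
}

#' @export
plot.gmm1d <- function(x, breaks = 50, ...) {
  h <- graphics::hist(x$values, breaks = breaks, freq = FALSE,
                      main = "1D Gaussian mixture",
                      xlab = "value", border = "grey70", ...)
  xx <- seq(min(x$values), max(x$values), length.out = 512)
  graphics::lines(xx, x$weights[1] * dnorm(xx, x$means[1], x$stdevs[1]),
                  col = "forestgreen", lwd = 2)
  graphics::lines(xx, x$weights[2] * dnorm(xx, x$means[2], x$stdevs[2]),
                  col = "firebrick", lwd = 2)
  thr <- tryCatch(decision_boundary(x), error = function(e) NULL)
  if (!is.null(thr)) graphics::abline(v = thr$value, lty = 2)
  invisible(h)
}

#' Equiprobable decision boundary of a two-component mixture
#'
#' Solves `w1 * phi(x | m1, s1) = w2 * phi(x | m2, s2)` — the value at
#' which both components are equiprobable — and returns the root lying
#' between the two component means. Taking logs this is a quadratic in `x`
#' (linear when the standard deviations are equal).
#'
#' @param model a [fit_gmm2()] fit with distinct component means.
#' @return an object of class `gmm_threshold`: list with `value`,
#'   `bracketing` (the two means) and `posterior_at_threshold`.
#' @export
decision_boundary <- function(model) {
  w <- model$weights; mu <- model$means; s <- model$stdevs
  if (abs(mu[2] - mu[1]) < 1e-12)
    stop("no decision boundary: component means are equal")
  # log w1 - log s1 - (x-m1)^2/(2 s1^2) = log w2 - log s2 - (x-m2)^2/(2 s2^2)
  a <- 1 / (2 * s[2]^2) - 1 / (2 * s[1]^2)
  b <- mu[1] / s[1]^2 - mu[2] / s[2]^2
  cc <- mu[2]^2 / (2 * s[2]^2) - mu[1]^2 / (2 * s[1]^2) +
    log(w[1] / s[1]) - log(w[2] / s[2])
  if (abs(a) < 1e-14) {
    roots <- -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) roots <- numeric(0)
    else roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  lo <- min(mu); hi <- max(mu)
  inside <- roots[roots >= lo - 1e-12 & roots <= hi + 1e-12]
  if (length(inside) == 0L)
    stop("no equiprobable boundary between the component means ",
         "(extreme weight/variance asymmetry); fall back to the ",
         "posterior-argmax rule")
  value <- inside[1]
  post <- predict(model, value, type = "posterior")
  structure(list(value = value, bracketing = mu,
                 posterior_at_threshold = as.numeric(post)),
            class = "gmm_threshold")
}

#' @export
print.gmm_threshold <- function(x, ...) {
  cat("equiprobable threshold:", format(x$value), "between means",
      format(x$bracketing[1]), "and", format(x$bracketing[2]), "\n")
  invisible(x)
}

#' Threshold values into below/above labels
#'
#' Values strictly greater than the threshold are labeled `"above"`; ties
#' go `"below"` (i.e. are kept by removal stages, which discard the
#' `"above"` group).
#'
#' @param values numeric vector.
#' @param threshold a [decision_boundary()] result or a plain number.
#' @return factor with levels `below`, `above`.
#' @export
classify <- function(values, threshold) {
  thr <- if (inherits(threshold, "gmm_threshold")) threshold$value
  else as.double(threshold)
  if (!is.finite(thr)) stop("threshold must be finite")
  factor(ifelse(values > thr, "above", "below"), levels = c("below", "above"))
}
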