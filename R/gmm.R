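#' @title One-dimensional Gaussian mixture by expectation-maximization
#' @name gmm
#' @description From-scratch univariate Gaussian mixture fitting used to
#'   separate the background prey population from the bait-bound population
#'   on the pooled log2 bait-normalized scale. The E-step is computed in log
#'   space for numerical stability; fits are returned in canonical form with
#'   means in ascending order.
NULL

# log(sum(exp(m[i, ]))) row-wise, stable; column loop beats apply() for
# the small k this package sees
.logsumexp_rows <- function(m) {
  mx <- m[, 1L]
  for (j in seq_len(ncol(m))[-1L]) mx <- pmax(mx, m[, j])
  mx + log(rowSums(exp(m - mx)))
}

.gmm_log_components <- function(x, weights, means, variances) {
  k <- length(weights)
  lc <- matrix(0, nrow = length(x), ncol = k)
  for (j in seq_len(k)) {
    lc[, j] <- log(weights[j]) +
      stats::dnorm(x, means[j], sqrt(variances[j]), log = TRUE)
  }
  lc
}

.gmm_loglik <- function(x, weights, means, variances) {
  sum(.logsumexp_rows(.gmm_log_components(x, weights, means, variances)))
}

# one EM run from a given mean initialization; returns parameters, the
# log-likelihood trace, and convergence flag
.em_run <- function(x, k, means0, tol, max_iter, var_floor) {
  n <- length(x)
  weights <- rep(1 / k, k)
  means <- means0
  variances <- rep(max(stats::var(x), var_floor), k)
  ll_old <- -Inf
  trace <- numeric(max_iter)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    lc <- .gmm_log_components(x, weights, means, variances)
    lse <- .logsumexp_rows(lc)
    ll <- sum(lse)
    trace[iter] <- ll
    resp <- exp(lc - lse)            # n x k responsibilities
    nk <- colSums(resp)
    weights <- nk / n
    means <- colSums(resp * x) / nk
    for (j in seq_len(k)) {
      variances[j] <- max(sum(resp[, j] * (x - means[j])^2) / nk[j], var_floor)
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  ll_final <- .gmm_loglik(x, weights, means, variances)
  list(weights = weights, means = means, variances = variances,
       log_likelihood = ll_final, n_iter = iter, converged = converged,
       ll_trace = c(trace[seq_len(iter)], ll_final))
}

#' Fit a univariate Gaussian mixture by EM
#'
#' Fits a `k`-component mixture to pooled log2 bait-normalized observations.
#' The default initialization is deterministic: component means at the
#' (2j-1)/(2k) sample quantiles with equal weights and the pooled sample
#' variance; additional restarts perturb those means with a seeded
#' generator, and the restart with the highest log-likelihood wins.
#' Convergence is declared when the absolute change in log-likelihood falls
#' below `tol`. Component variances are floored at `var_floor` to prevent a
#' component collapsing onto a single observation.
#'
#' @param observations numeric vector of finite values; at least `5 * k`
#'   observations are required and they must not all be identical.
#' @param k number of components (default 2: background vs bound).
#' @param tol absolute log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter maximum EM iterations per restart (default 2000).
#' @param var_floor minimum component variance (default 1e-6, log2^2 units).
#' @param n_restarts number of initializations, the first always the
#'   deterministic quantile one (default 5).
#' @param seed integer seed driving the restart perturbations; recorded in
#'   the fit (default 0).
#' @param init `"quantile"` (default) or `"random"`; `"random"` draws all
#'   initial means from the data range instead of anchoring the first
#'   restart at the quantiles.
#' @return An object of class `gmm_fit`: `k`, `weights`, `means` (ascending),
#'   `variances`, `log_likelihood`, `n_obs`, `n_iter`, `converged`, `seed`,
#'   and `ll_trace` (per-iteration log-likelihood of the winning restart).
#' @examples
#' set.seed(7)
#' x <- c(rnorm(450, -4), rnorm(50, 0))
#' fit <- fit_gmm(x, k = 2)
#' fit$means
#' @export
fit_gmm <- function(observations, k = 2L, tol = 1e-8, max_iter = 2000L,
                    var_floor = 1e-6, n_restarts = 5L, seed = 0L,
                    init = c("quantile", "random")) {
  init <- match.arg(init)
  x <- as.numeric(observations)
  if (anyNA(x) || any(!is.finite(x))) {
    stop("observations must be finite", call. = FALSE)
  }
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (tol <= 0 || max_iter < 1L) {
    stop("tol must be > 0 and max_iter >= 1", call. = FALSE)
  }
  n <- length(x)
  if (n < 5L * k) {
    stop("need at least ", 5L * k, " observations to fit k = ", k,
         " components (got ", n, ")", call. = FALSE)
  }
  if (length(unique(x)) == 1L) {
    stop("all observations are identical; no mixture to fit", call. = FALSE)
  }

  qmeans <- as.numeric(stats::quantile(x, probs = (2 * seq_len(k) - 1) / (2 * k),
                                       names = FALSE, type = 7))
  sdx <- stats::sd(x)
  n_restarts <- max(1L, as.integer(n_restarts))
  # all restart perturbations drawn from one seeded stream, without
  # disturbing the caller's global RNG state
  perturb <- .with_local_seed(seed, function() {
    matrix(stats::rnorm(n_restarts * k, 0, sdx / 2), nrow = n_restarts)
  })
  best <- NULL
  for (r in seq_len(n_restarts)) {
    means0 <- if (r == 1L && init == "quantile") {
      qmeans
    } else {
      qmeans + perturb[r, ]
    }
    run <- .em_run(x, k, means0, tol, max_iter, var_floor)
    if (is.null(best) || run$log_likelihood > best$log_likelihood) {
      best <- run
    }
  }

  ord <- order(best$means)
  structure(list(k = k,
                 weights = best$weights[ord],
                 means = best$means[ord],
                 variances = best$variances[ord],
                 log_likelihood = best$log_likelihood,
                 n_obs = n,
                 n_iter = best$n_iter,
                 converged = best$converged,
                 seed = as.integer(seed),
                 ll_trace = best$ll_trace),
            class = "gmm_fit")
}

# evaluate f() under set.seed(seed), restoring the caller's RNG state after
.with_local_seed <- function(seed, f) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  f()
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat("Gaussian mixture fit (k = ", x$k, ", n = ", x$n_obs, ")\n", sep = "")
  cat(format(gmm_summary_text(x)), sep = "\n")
  invisible(x)
}

#' Component posterior probabilities under a fitted mixture
#'
#' Bayes-rule component memberships
#' \eqn{p_j(x) = w_j \phi(x; m_j, v_j) / \sum_i w_i \phi(x; m_i, v_i)},
#' evaluated stably in log space. Rows sum to 1 for every finite `x`.
#'
#' @param fit a `gmm_fit`.
#' @param x numeric vector of evaluation points.
#' @return numeric matrix, `length(x)` rows by `fit$k` columns.
#' @export
gmm_posterior <- function(fit, x) {
  stopifnot(inherits(fit, "gmm_fit"))
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("x must be finite", call. = FALSE)
  lc <- .gmm_log_components(x, fit$weights, fit$means, fit$variances)
  mx <- lc[, 1L]
  for (j in seq_len(ncol(lc))[-1L]) mx <- pmax(mx, lc[, j])
  e <- exp(lc - mx)
  post <- e / rowSums(e)
  colnames(post) <- paste0("component", seq_len(fit$k))
  post
}

#' Index of the high-abundance component
#'
#' The component representing bait-bound preys is the one with the largest
#' mean on the log2 bait-normalized scale (higher normalized peptide counts).
#' Mean ties are broken by larger weight, then by lowest index.
#'
#' @param fit a `gmm_fit`.
#' @return integer component index in `1..fit$k`.
#' @export
select_high_component <- function(fit) {
  stopifnot(inherits(fit, "gmm_fit"))
  top <- which(fit$means == max(fit$means))
  if (length(top) > 1L) {
    top <- top[fit$weights[top] == max(fit$weights[top])]
  }
  as.integer(top[1L])
}

#' Bayesian information criterion of a mixture fit
#'
#' `BIC = (3k - 1) ln(n) - 2 logL`, counting the free parameters of a
#' univariate k-component mixture: k-1 weights, k means, k variances.
#' Smaller is better; used for optional model-order selection.
#'
#' @param fit a `gmm_fit`.
#' @return BIC value.
#' @export
gmm_bic <- function(fit) {
  stopifnot(inherits(fit, "gmm_fit"))
  (3 * fit$k - 1) * log(fit$n_obs) - 2 * fit$log_likelihood
}

#' Choose the number of components by BIC
#'
#' Fits each candidate `k` and returns the fit with the smallest
#' [gmm_bic()]. Off by default in the pipeline, which fixes k = 2
#' (background vs bound).
#'
#' @param observations numeric vector passed to [fit_gmm()].
#' @param k_values candidate component counts (default 1:3).
#' @param ... further arguments to [fit_gmm()].
#' @return the BIC-best `gmm_fit`, with the full candidate table attached as
#'   attribute `"bic_table"`.
#' @export
select_k_bic <- function(observations, k_values = 1:3, ...) {
  fits <- lapply(k_values, function(k) fit_gmm(observations, k = k, ...))
  bics <- vapply(fits, gmm_bic, numeric(1))
  best <- fits[[which.min(bics)]]
  attr(best, "bic_table") <- data.frame(k = as.integer(k_values), bic = bics)
  best
}

#' Plain-text key-value summary of a fit, for run logs
#'
#' @param fit a `gmm_fit`.
#' @return character vector of `key: value` lines.
#' @export
gmm_summary_text <- function(fit) {
  c(sprintf("k: %d", fit$k),
    sprintf("weights: %s", paste(formatC(fit$weights, digits = 8, format = "g"),
                                 collapse = " ")),
    sprintf("means: %s", paste(formatC(fit$means, digits = 8, format = "g"),
                               collapse = " ")),
    sprintf("variances: %s", paste(formatC(fit$variances, digits = 8,
                                           format = "g"), collapse = " ")),
    sprintf("log_likelihood: %.8f", fit$log_likelihood),
    sprintf("n_obs: %d", fit$n_obs),
    sprintf("n_iter: %d", fit$n_iter),
    sprintf("converged: %s", tolower(as.character(fit$converged))),
    sprintf("seed: %d", fit$seed))
}
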