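## Expectation-Maximization fitting of full-covariance Gaussian mixtures,
## with multi-restart initialization, ridge-regularized covariances, and
## BIC-based selection of the number of components.

#' Fit a Gaussian mixture model by EM
#'
#' Full-covariance EM with deterministic seeded restarts. Each restart draws
#' `K` distinct rows as initial centers, assigns every row to its nearest
#' center, and initializes weights/means/covariances from that hard
#' partition; EM then alternates responsibilities (E) and weighted moment
#' updates (M) until the log-likelihood change falls below `tol` (relative)
#' or `max_iter` is reached. Every M-step covariance receives a ridge of
#' `ridge * trace(S)/d` on the diagonal to keep it positive definite; a
#' restart whose components degenerate (vanishing weight or failed Cholesky)
#' is abandoned and reseeded. The best restart by final log-likelihood is
#' returned.
#'
#' For `K = 1` the maximum-likelihood solution is closed-form (sample mean
#' and ML covariance) and no iteration is run.
#'
#' @param x numeric matrix (rows = units, columns = indicators), typically
#'   z-scored.
#' @param K number of mixture components, `>= 1`; must not exceed `nrow(x)`.
#' @param seed integer seed controlling the restarts.
#' @param n_restarts number of seeded restarts (default 10).
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter maximum EM iterations per restart (default 500).
#' @param ridge covariance regularization factor (default 1e-6).
#' @return An object of class `wvi_gmm`: list with `K`, `weights`, `means`
#'   (K x d), `covariances` (list of d x d), `log_likelihood`, `bic`,
#'   `responsibilities` (n x K, rows on the simplex), `assignments` (argmax
#'   responsibility), `loglik_trace` (per accepted iteration of the winning
#'   restart), `n_iter`, `n_params`.
#' @export
fit_gmm_em <- function(x, K, seed = 1L, n_restarts = 10L, tol = 1e-8,
                       max_iter = 500L, ridge = 1e-6) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x); d <- ncol(x)
  if (K < 1L) stop("K must be >= 1")
  if (n < K) stop("fewer rows (", n, ") than components (", K, ")")

  if (K == 1L) {
    mu <- colMeans(x)
    xc <- sweep(x, 2L, mu, "-")
    S <- crossprod(xc) / n
    S <- S + diag(ridge * sum(diag(S)) / d, d)
    ll <- sum(dmvnorm_log(x, mu, S))
    return(new_gmm(K = 1L, weights = 1, means = matrix(mu, 1L, d),
                   covariances = list(S), ll = ll,
                   resp = matrix(1, n, 1L), trace = ll, n_iter = 0L,
                   n = n, d = d, colnames = colnames(x)))
  }

  best <- NULL
  attempt <- 0L
  done <- 0L
  while (done < n_restarts && attempt < n_restarts * 10L) {
    attempt <- attempt + 1L
    set.seed((seed + attempt * 131L) %% .Machine$integer.max)
    fit <- try(em_once(x, K, tol, max_iter, ridge), silent = TRUE)
    if (inherits(fit, "try-error")) next
    done <- done + 1L
    if (is.null(best) || fit$ll > best$ll) best <- fit
  }
  if (is.null(best))
    stop("EM failed: all ", attempt, " restart attempts degenerated")

  new_gmm(K = K, weights = best$weights, means = best$means,
          covariances = best$covs, ll = best$ll, resp = best$resp,
          trace = best$trace, n_iter = length(best$trace),
          n = n, d = d, colnames = colnames(x))
}

new_gmm <- function(K, weights, means, covariances, ll, resp, trace, n_iter,
                    n, d, colnames = NULL) {
  p <- gmm_n_params(K, d)
  if (!is.null(colnames)) {
    colnames(means) <- colnames
    covariances <- lapply(covariances, function(S) {
      dimnames(S) <- list(colnames, colnames); S
    })
  }
  structure(
    list(K = K, weights = weights, means = means, covariances = covariances,
         log_likelihood = ll, bic = p * log(n) - 2 * ll,
         responsibilities = resp,
         assignments = max.col(resp, ties.method = "first"),
         loglik_trace = trace, n_iter = n_iter, n_params = p, n = n, d = d),
    class = "wvi_gmm"
  )
}

#' @export
print.wvi_gmm <- function(x, ...) {
  cat(sprintf("<wvi_gmm> K=%d, d=%d, n=%d; logLik %.3f, BIC %.3f (%d params, %d iterations)\n",
              x$K, x$d, x$n, x$log_likelihood, x$bic, x$n_params, x$n_iter))
  cat("  weights:", paste(sprintf("%.3f", x$weights), collapse = " "), "\n")
  invisible(x)
}

## free parameters of a K-component full-covariance mixture in d dimensions
gmm_n_params <- function(K, d) (K - 1L) + K * d + K * d * (d + 1L) / 2L

em_once <- function(x, K, tol, max_iter, ridge) {
  n <- nrow(x); d <- ncol(x)
  centers <- x[sample.int(n, K), , drop = FALSE]
  dist2 <- sapply(seq_len(K), function(k)
    rowSums(sweep(x, 2L, centers[k, ], "-")^2))
  hard <- max.col(-dist2, ties.method = "first")
  Sg <- stats::cov(x) * (n - 1) / n

  weights <- numeric(K)
  means <- matrix(0, K, d)
  covs <- vector("list", K)
  for (k in seq_len(K)) {
    rows <- which(hard == k)
    weights[k] <- max(length(rows), 1) / n
    means[k, ] <- if (length(rows)) colMeans(x[rows, , drop = FALSE]) else
      centers[k, ]
    Sk <- if (length(rows) > d) {
      xc <- sweep(x[rows, , drop = FALSE], 2L, means[k, ], "-")
      crossprod(xc) / length(rows)
    } else Sg
    covs[[k]] <- regularize_cov(Sk, ridge, Sg)
  }
  weights <- weights / sum(weights)

  trace <- numeric(0)
  ll_prev <- -Inf
  for (iter in seq_len(max_iter)) {
    ## E-step
    logdens <- vapply(seq_len(K), function(k)
      dmvnorm_log(x, means[k, ], covs[[k]]) + log(weights[k]),
      numeric(n))
    mx <- apply(logdens, 1L, max)
    lse <- mx + log(rowSums(exp(logdens - mx)))
    ll <- sum(lse)
    trace <- c(trace, ll)
    resp <- exp(logdens - lse)

    if (is.finite(ll_prev) && abs(ll - ll_prev) <= tol * (1 + abs(ll))) break
    ll_prev <- ll

    ## M-step
    Nk <- colSums(resp)
    if (any(Nk < d + 1e-3)) stop("degenerate component (vanishing weight)")
    weights <- Nk / n
    for (k in seq_len(K)) {
      means[k, ] <- colSums(x * resp[, k]) / Nk[k]
      xc <- sweep(x, 2L, means[k, ], "-")
      Sk <- crossprod(xc, xc * resp[, k]) / Nk[k]
      covs[[k]] <- regularize_cov(Sk, ridge, Sg)
    }
  }
  list(ll = ll, weights = weights, means = means, covs = covs, resp = resp,
       trace = trace)
}

regularize_cov <- function(S, ridge, fallback) {
  d <- ncol(S)
  tr <- sum(diag(S))
  if (!is.finite(tr) || tr <= 0) S <- fallback
  S <- S + diag(ridge * max(sum(diag(S)), .Machine$double.eps) / d, d)
  if (inherits(try(chol(S), silent = TRUE), "try-error"))
    stop("singular covariance")
  S
}

## log density of rows of x under N(mu, S), via Cholesky
dmvnorm_log <- function(x, mu, S) {
  d <- length(mu)
  ch <- chol(S)
  xc <- sweep(x, 2L, mu, "-")
  y <- backsolve(ch, t(xc), transpose = TRUE)
  -0.5 * colSums(y^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
}

#' Select the number of mixture components by BIC
#'
#' Fits [fit_gmm_em()] for every `K` in `k_range` and returns the fit
#' minimizing `BIC = p ln(n) - 2 lnL`, where `p = (K-1) + K d + K d(d+1)/2`
#' is the free-parameter count of a full-covariance mixture. Under this sign
#' convention smaller is better: the criterion trades goodness of fit
#' against a complexity penalty growing with `K`.
#'
#' @param x numeric matrix (typically z-scored indicators).
#' @param k_range integer vector of candidate component counts.
#' @param seed integer seed; each `K` derives its own restart stream.
#' @param ... passed to [fit_gmm_em()].
#' @return List with `K` (selected), `model` (the winning `wvi_gmm`), `bic`
#'   (named numeric over `k_range`), `fits` (all models).
#' @export
select_k_bic <- function(x, k_range = 1:6, seed = 1L, ...) {
  if (length(k_range) == 0L) stop("`k_range` must be nonempty")
  fits <- list()
  bic <- stats::setNames(rep(NA_real_, length(k_range)), k_range)
  errors <- character(0)
  for (i in seq_along(k_range)) {
    K <- k_range[i]
    fit <- try(fit_gmm_em(x, K, seed = (seed + 977L * K) %% .Machine$integer.max,
                          ...), silent = TRUE)
    if (inherits(fit, "try-error")) {
      errors <- c(errors, sprintf("K=%d: %s", K, attr(fit, "condition")$message))
      next
    }
    fits[[as.character(K)]] <- fit
    bic[i] <- fit$bic
  }
  if (all(is.na(bic)))
    stop("mixture selection failed for every K: ", paste(errors, collapse = "; "))
  best <- k_range[which.min(bic)]
  list(K = best, model = fits[[as.character(best)]], bic = bic, fits = fits)
}
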