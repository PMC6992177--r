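## Cross-correlation, z-normalization, PCA with three component-retention
## rules, cluster departure profiles and cluster-wise PCA.

#' Cross-correlation matrix of the vulnerability indicators
#'
#' Pairwise-complete Pearson correlations between indicator columns, with a
#' display flag for coefficients whose magnitude exceeds `flag_threshold`
#' (the conventional 0.4 highlight). Zero-variance columns yield `NA`
#' coefficients and are reported in the `degenerate` attribute.
#'
#' @param table numeric data.frame/matrix of per-unit indicator values (a
#'   `unit_id` column, if present, is dropped).
#' @param flag_threshold magnitude above which a correlation is flagged.
#' @return An object of class `wvi_corr`: list with `r` (correlation
#'   matrix), `flagged` (logical matrix, off-diagonal `|r| >
#'   flag_threshold`), `n` (pairwise complete counts), `degenerate`
#'   (zero-variance column names).
#' @export
correlation_matrix <- function(table, flag_threshold = 0.4) {
  x <- drop_unit_id(table)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  sds <- apply(x, 2L, stats::sd, na.rm = TRUE)
  degenerate <- colnames(x)[!is.na(sds) & sds == 0]
  r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  if (length(degenerate)) {
    r[degenerate, ] <- NA_real_
    r[, degenerate] <- NA_real_
  }
  diag(r) <- ifelse(colnames(x) %in% degenerate, NA_real_, 1)
  ok <- !is.na(x)
  n <- crossprod(ok)
  flagged <- !is.na(r) & abs(r) > flag_threshold
  diag(flagged) <- FALSE
  structure(list(r = r, flagged = flagged, n = n, degenerate = degenerate),
            class = "wvi_corr")
}

#' @export
print.wvi_corr <- function(x, ...) {
  cat(sprintf("<wvi_corr> %d variables; %d flagged pairs (|r| > threshold)\n",
              ncol(x$r), sum(x$flagged) / 2L))
  print(round(x$r, 2))
  invisible(x)
}

#' Z-normalize an indicator table
#'
#' Subtracts each column's mean and divides by its sample (n-1) standard
#' deviation, the convention used consistently across the correlation, PCA
#' and clustering steps.
#'
#' @param table numeric data.frame/matrix (a `unit_id` column is dropped).
#' @return Numeric matrix with column means 0 and SDs 1; attributes `center`
#'   and `scale` hold the column statistics.
#' @export
znormalize <- function(table) {
  x <- drop_unit_id(table)
  mu <- colMeans(x, na.rm = TRUE)
  sdv <- apply(x, 2L, stats::sd, na.rm = TRUE)
  zero <- which(!is.na(sdv) & sdv == 0)
  if (length(zero))
    stop("zero-variance column(s): ", paste(colnames(x)[zero], collapse = ", "))
  z <- sweep(sweep(x, 2L, mu, "-"), 2L, sdv, "/")
  attr(z, "center") <- mu
  attr(z, "scale") <- sdv
  z
}

#' Principal component analysis of the indicator table
#'
#' With `scale = TRUE` (the default used throughout the pipeline), the
#' eigen decomposition of the correlation matrix -- equivalently the
#' covariance of the z-scored data -- appropriate because the indicators
#' carry incommensurate units. With `scale = FALSE`, the decomposition of
#' the sample covariance of the centered data (e.g. for data already on a
#' common scale). Rows with any missing value are dropped (complete-case
#' analysis) and the count reported. Component signs follow a deterministic
#' convention: the largest-magnitude loading of each component is made
#' positive.
#'
#' @param table numeric data.frame/matrix of per-unit indicator values.
#' @param scale decompose the correlation (`TRUE`, default) or covariance
#'   (`FALSE`) matrix.
#' @return An object of class `wvi_pca`: list with `loadings` (variables x
#'   components, orthonormal), `eigenvalues` (descending, clipped at 0),
#'   `proportion` (variance fractions, summing to 1), `scores` (complete
#'   rows x components), `matrix` (the decomposed correlation/covariance),
#'   `n_used`, `n_dropped`.
#' @export
pca_indicators <- function(table, scale = TRUE) {
  x <- drop_unit_id(table)
  cc <- stats::complete.cases(x)
  n_dropped <- sum(!cc)
  x <- x[cc, , drop = FALSE]
  if (nrow(x) < 2L) stop("PCA needs at least 2 complete rows")
  if (scale) {
    y <- znormalize(x)
    M <- stats::cor(x)
  } else {
    y <- sweep(x, 2L, colMeans(x), "-")
    M <- stats::cov(x)
  }
  e <- eigen(M, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  load <- e$vectors
  for (k in seq_len(ncol(load))) {
    mx <- which.max(abs(load[, k]))
    if (load[mx, k] < 0) load[, k] <- -load[, k]
  }
  dimnames(load) <- list(colnames(x), paste0("PC", seq_len(ncol(load))))
  structure(
    list(loadings = load,
         eigenvalues = vals,
         proportion = vals / sum(vals),
         scores = y %*% load,
         matrix = M,
         n_used = nrow(x),
         n_dropped = n_dropped),
    class = "wvi_pca"
  )
}

#' @export
print.wvi_pca <- function(x, ...) {
  cat(sprintf("<wvi_pca> %d variables, %d rows used (%d dropped)\n",
              nrow(x$loadings), x$n_used, x$n_dropped))
  cat("  proportion of variance:",
      paste(sprintf("%.2f", x$proportion), collapse = " "), "\n")
  invisible(x)
}

#' Component-retention rules
#'
#' Three standard rules for choosing how many principal components to
#' retain:
#' \describe{
#'   \item{`scree`}{the deflection point of the eigenvalue scree, located as
#'     the index of the maximum second difference of the descending
#'     eigenvalues (first index on ties).}
#'   \item{`cumulative`}{the smallest count whose cumulative variance
#'     fraction exceeds `threshold` (default 0.85).}
#'   \item{`above_mean`}{the count of eigenvalues strictly greater than the
#'     mean eigenvalue; 0 (with a warning) when all eigenvalues are equal.}
#' }
#'
#' @param eigenvalues numeric vector, descending.
#' @param rule one of `"scree"`, `"cumulative"`, `"above_mean"`.
#' @param threshold cumulative variance threshold for `rule = "cumulative"`.
#' @return Integer count of retained components.
#' @examples
#' p <- c(0.31, 0.17, 0.13, 0.10, 0.09, 0.06, 0.06, 0.05, 0.03, 0.01)
#' select_components(p, "cumulative")  # 6
#' @export
select_components <- function(eigenvalues,
                              rule = c("scree", "cumulative", "above_mean"),
                              threshold = 0.85) {
  rule <- match.arg(rule)
  ev <- as.numeric(eigenvalues)
  if (is.unsorted(rev(ev))) stop("`eigenvalues` must be descending")
  switch(rule,
    scree = {
      if (length(ev) < 3L) stop("scree rule needs at least 3 eigenvalues")
      d2 <- diff(diff(ev))                # d2[k] at interior index k+1
      as.integer(which.max(d2) + 1L)
    },
    cumulative = {
      cum <- cumsum(ev / sum(ev))
      as.integer(which(cum > threshold)[1L])
    },
    above_mean = {
      k <- sum(ev > mean(ev))
      if (k == 0L) warning("all eigenvalues equal: above_mean rule retains 0 (degenerate)")
      as.integer(k)
    }
  )
}

#' Cluster departure profiles
#'
#' For each cluster, the mean z-score of every indicator over the cluster's
#' units -- the departure of the cluster from the global mean in
#' standard-deviation units -- plus the sum of those means, a scalar summary
#' of how much more (positive) or less (negative) vulnerable the cluster is
#' than the domain average. Size-weighted departures sum to zero per
#' indicator by construction.
#'
#' @param z z-scored indicator matrix (from [znormalize()]).
#' @param assignments integer/factor cluster label per row of `z`.
#' @return An object of class `wvi_departures`: list with `means` (clusters
#'   x indicators), `sum` (named numeric per cluster), `size` (cluster
#'   sizes).
#' @export
cluster_departures <- function(z, assignments) {
  z <- as.matrix(z)
  if (length(assignments) != nrow(z))
    stop("`assignments` must cover every row of `z`")
  labs <- sort(unique(assignments))
  means <- t(vapply(labs, function(g) colMeans(z[assignments == g, , drop = FALSE]),
                    numeric(ncol(z))))
  rownames(means) <- as.character(labs)
  structure(
    list(means = means,
         sum = stats::setNames(rowSums(means), as.character(labs)),
         size = stats::setNames(as.integer(table(assignments)[as.character(labs)]),
                                as.character(labs))),
    class = "wvi_departures"
  )
}

#' @export
print.wvi_departures <- function(x, ...) {
  cat("<wvi_departures>\n")
  for (g in rownames(x$means))
    cat(sprintf("  cluster %s (n=%d): sum of departures %+0.2f\n",
                g, x$size[[g]], x$sum[[g]]))
  invisible(x)
}

#' Per-cluster PCA
#'
#' Runs [pca_indicators()] independently on each cluster's rows. Clusters
#' with fewer than `min_n` rows are skipped with a warning.
#'
#' @param table numeric data.frame/matrix of per-unit indicator values.
#' @param assignments cluster label per row.
#' @param min_n minimum cluster size to analyze (default 3).
#' @return Named list of `wvi_pca` objects, one per analyzed cluster.
#' @export
clusterwise_pca <- function(table, assignments, min_n = 3L) {
  x <- drop_unit_id(table)
  if (length(assignments) != nrow(x))
    stop("`assignments` must cover every row of the table")
  out <- list()
  for (g in sort(unique(assignments))) {
    rows <- which(assignments == g)
    if (length(rows) < min_n) {
      warning("cluster ", g, " has ", length(rows), " rows (< ", min_n,
              "): skipped")
      next
    }
    out[[as.character(g)]] <- pca_indicators(x[rows, , drop = FALSE])
  }
  out
}

drop_unit_id <- function(table) {
  if (is.data.frame(table)) {
    table <- table[, setdiff(names(table), "unit_id"), drop = FALSE]
    as.matrix(table)
  } else {
    as.matrix(table)
  }
}
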