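#' Pearson correlation matrix with per-group-pair summary statistics
#'
#' Computes the sample-by-sample Pearson correlation over all clusters, then
#' summarises the coefficients per comparison group: within a group of k
#' samples the choose(k, 2) unordered pairs are used; across two groups of
#' k1 and k2 samples the full k1 x k2 cartesian product is used (so 4 vs 4
#' arrays give 6, 6 and 16 comparisons).
#'
#' @param m numeric matrix of log2 signals, samples in columns.
#' @param groups character vector of group labels, one per column (or named
#'   and matched against colnames).
#' @return list of class `pearson_summary`: `correlations` (symmetric matrix,
#'   unit diagonal) and `summaries` (data.frame with `group_a`, `group_b`,
#'   `n`, `min`, `max`, `mean`, `sd`, `se`), where `se = sd / sqrt(n)`.
#' @export
pearson_summary <- function(m, groups) {
  stopifnot(is.matrix(m))
  if (!is.null(names(groups))) groups <- groups[colnames(m)]
  if (length(groups) != ncol(m)) stop("need one group label per sample")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance sample(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  cc <- stats::cor(m)
  glev <- unique(groups)
  summaries <- list()
  for (i in seq_along(glev)) {
    for (j in i:length(glev)) {
      ga <- glev[i]; gb <- glev[j]
      ia <- which(groups == ga); ib <- which(groups == gb)
      if (ga == gb) {
        if (length(ia) < 2L) next
        pairs <- utils::combn(ia, 2L)
        vals <- cc[cbind(pairs[1L, ], pairs[2L, ])]
      } else {
        vals <- as.vector(cc[ia, ib, drop = FALSE])
      }
      summaries[[length(summaries) + 1L]] <- data.frame(
        group_a = ga, group_b = gb, n = length(vals),
        min = min(vals), max = max(vals), mean = mean(vals),
        sd = stats::sd(vals), se = stats::sd(vals) / sqrt(length(vals)),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(correlations = cc,
                 summaries = do.call(rbind, summaries)),
            class = "pearson_summary")
}

#' @export
print.pearson_summary <- function(x, ...) {
  cat("Pearson concordance over", nrow(x$correlations), "samples\n")
  print(x$summaries, row.names = FALSE)
  invisible(x)
}

#' MvA (log-ratio vs average) records between two group mean profiles
#'
#' Per cluster, `M = mean_a - mean_b` (log2 difference) and
#' `A = (mean_a + mean_b) / 2` (average log2 signal). A cluster is a fold
#' outlier when `|M| >= fold_threshold`; the default threshold 1 marks a
#' 2-fold difference (the lines drawn on MvA plots).
#'
#' @param mean_a,mean_b named numeric vectors of per-cluster mean log2
#'   signals over the same cluster universe.
#' @param fold_threshold |M| cutoff defining an outlier (default 1, inclusive).
#' @return list: `records` (data.frame `cluster_id`, `A`, `M`), `n_outliers`,
#'   `outlier_ids`, `fold_threshold`.
#' @export
mva <- function(mean_a, mean_b, fold_threshold = 1) {
  if (is.null(names(mean_a)) || is.null(names(mean_b)))
    stop("mean vectors must be named by cluster id")
  if (!setequal(names(mean_a), names(mean_b)))
    stop("cluster universes differ between the two groups")
  mean_b <- mean_b[names(mean_a)]
  M <- mean_a - mean_b
  A <- (mean_a + mean_b) / 2
  out <- abs(M) >= fold_threshold
  list(records = data.frame(cluster_id = names(mean_a), A = unname(A),
                            M = unname(M), stringsAsFactors = FALSE),
       n_outliers = sum(out),
       outlier_ids = names(mean_a)[out],
       fold_threshold = fold_threshold)
}

#' Mean squared distance between ranked cluster profiles
#'
#' Orders clusters by descending reference mean (the ranked-profile view) and
#' returns `MSD = mean((reference - comparison)^2)` over the identity pairing
#' of clusters; the ordering fixes the reporting/plotting order but does not
#' change the value.
#'
#' @param reference,comparison named numeric vectors of per-cluster mean
#'   signals over the same cluster universe.
#' @return list: `msd` (scalar) and `ranked` (data.frame `cluster_id`,
#'   `reference`, `comparison` in descending reference order).
#' @export
msd_ranked <- function(reference, comparison) {
  if (is.null(names(reference)) || is.null(names(comparison)))
    stop("profiles must be named by cluster id")
  if (!setequal(names(reference), names(comparison)))
    stop("cluster universes differ between reference and comparison")
  comparison <- comparison[names(reference)]
  ord <- order(reference, decreasing = TRUE)
  ranked <- data.frame(cluster_id = names(reference)[ord],
                       reference = unname(reference[ord]),
                       comparison = unname(comparison[ord]),
                       stringsAsFactors = FALSE)
  list(msd = mean((reference - comparison)^2), ranked = ranked)
}

#' Per-group binned frequencies of mean signal
#'
#' Histogram of per-cluster group-mean log2 signal with shared bin edges
#' across groups, the numerical content behind mean-signal histograms
#' comparing e.g. host-only to pure-human hybridisations.
#'
#' @param m numeric matrix of log2 signals, samples in columns.
#' @param groups group label per column (or named, matched on colnames).
#' @param bins number of bins (default 30) or a vector of breakpoints.
#' @return list: `breaks` and `counts` (bins x groups matrix; each column sums
#'   to the cluster count).
#' @export
signal_histogram <- function(m, groups, bins = 30) {
  stopifnot(is.matrix(m))
  if (nrow(m) == 0L) stop("empty matrix")
  if (!is.null(names(groups))) groups <- groups[colnames(m)]
  if (length(groups) != ncol(m)) stop("need one group label per sample")
  glev <- unique(groups)
  means <- sapply(glev, function(g)
    rowMeans(m[, groups == g, drop = FALSE]))
  if (is.null(dim(means))) means <- matrix(means, ncol = length(glev),
                                           dimnames = list(NULL, glev))
  rng <- range(means)
  breaks <- if (length(bins) > 1L) bins else
    seq(rng[1L] - 1e-9, rng[2L] + 1e-9, length.out = bins + 1L)
  counts <- sapply(glev, function(g)
    hist(means[, g], breaks = breaks, plot = FALSE)$counts)
  if (is.null(dim(counts))) counts <- matrix(counts, ncol = length(glev),
                                             dimnames = list(NULL, glev))
  list(breaks = breaks, counts = counts)
}

# Inverse of the trigamma function by Newton iteration (monotone decreasing on
# (0, Inf)); used by the moment estimator of the variance prior.
trigamma_inverse <- function(y) {
  stopifnot(y > 0)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) < 1e-10 * x) break
  }
  x
}

#' Empirical-Bayes moderated two-sample t-test
#'
#' Fits a two-group linear model per cluster and moderates the residual
#' variances toward a common prior: with per-cluster residual variance `s2`
#' on `d` degrees of freedom, the prior degrees of freedom `d0` and prior
#' variance `s02` are estimated by the method of moments on `log(s2)`
#' (matching the log-variance mean and spread to a scaled-F model), the
#' posterior variance is `(d0*s02 + d*s2) / (d0 + d)`, and the moderated t
#' statistic `t = dmean / (s_post * sqrt(1/n1 + 1/n2))` is referred to a t
#' distribution with `d0 + d` degrees of freedom (two-sided). P-values are
#' adjusted by [bh_adjust()].
#'
#' Limiting behaviour: `d0 -> 0` recovers the ordinary pooled two-sample t;
#' `d0 = Inf` (no excess spread in the observed log variances) gives every
#' cluster the common variance `s02`.
#'
#' @param m numeric matrix of cluster-level log2 signals, samples in columns.
#' @param groups two-level label per column (or named, matched on colnames);
#'   each group needs >= 2 samples.
#' @return list of class `moderated_t`: `table` (data.frame `cluster_id`,
#'   `logFC` = group1 - group2 mean difference, `t`, `p`, `adj_p`), and the
#'   hyperparameters `d0`, `s02`, residual df `d`.
#' @export
moderated_t_test <- function(m, groups) {
  stopifnot(is.matrix(m))
  if (!is.null(names(groups))) groups <- groups[colnames(m)]
  if (length(groups) != ncol(m)) stop("need one group label per sample")
  glev <- unique(groups)
  if (length(glev) != 2L) stop("exactly two groups required")
  i1 <- which(groups == glev[1L]); i2 <- which(groups == glev[2L])
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 samples")
  d <- n1 + n2 - 2L
  m1 <- rowMeans(m[, i1, drop = FALSE])
  m2 <- rowMeans(m[, i2, drop = FALSE])
  rss <- rowSums((m[, i1, drop = FALSE] - m1)^2) +
    rowSums((m[, i2, drop = FALSE] - m2)^2)
  s2 <- rss / d

  # method of moments on log variances
  ok <- is.finite(log(s2))
  if (!any(ok)) stop("all clusters have zero residual variance")
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / max(length(e) - 1L, 1L) - trigamma(d / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    s2_post <- (d0 * s02 + d * s2) / (d0 + d)
    df_total <- d0 + d
  } else {
    d0 <- Inf
    s02 <- exp(emean)
    s2_post <- rep(s02, length(s2))
    df_total <- Inf
  }
  logFC <- m1 - m2
  tstat <- logFC / sqrt(s2_post * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  tab <- data.frame(cluster_id = rownames(m), logFC = unname(logFC),
                    t = unname(tstat), p = unname(p),
                    adj_p = bh_adjust(unname(p)),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, d0 = d0, s02 = s02, d = d,
                 groups = glev), class = "moderated_t")
}

#' @export
print.moderated_t <- function(x, ...) {
  cat(sprintf("moderated t (%s vs %s): %d clusters, d0 = %.3g, s02 = %.3g\n",
              x$groups[1L], x$groups[2L], nrow(x$table), x$d0, x$s02))
  invisible(x)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjusted p-values (step-up: sort ascending, take
#' running minima of `p * N / rank` from the largest down, cap at 1), returned
#' in input order. Thin validated wrapper around
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order; always `>= p`, in \[0, 1\], and
#'   monotone in raw-p rank.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
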