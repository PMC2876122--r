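#' Quantile normalisation of a linear-scale probe matrix
#'
#' Forces every column to the same empirical distribution: each column's
#' sorted values are replaced by the row-wise mean of the sorted input
#' columns; ties within a column receive the mean of the target values they
#' span. Delegates to [limma::normalizeQuantiles()] (with `ties = TRUE`),
#' after validating positivity.
#'
#' @param m numeric matrix, linear scale, strictly positive, >= 2 columns.
#' @return normalised matrix, same dimnames.
#' @export
quantile_normalise <- function(m) {
  stopifnot(is.matrix(m))
  if (ncol(m) < 2L) stop("quantile normalisation needs at least 2 columns")
  if (any(!is.finite(m)) || any(m <= 0))
    stop("quantile normalisation requires finite positive (linear-scale) values")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Floor-and-log transform ("RMA-16" style)
#'
#' Low-intensity stabilisation by flooring linear-scale values at `floor`
#' (default 16) before the log2 transform, emulating the low-end thresholding
#' behaviour of floored RMA variants.
#'
#' @param m numeric matrix, linear scale.
#' @param floor linear-scale floor (default 16, so the log2 floor is 4).
#' @return log2-scale matrix.
#' @export
rma16_log <- function(m, floor = 16) {
  stopifnot(is.matrix(m) || is.numeric(m))
  log2(pmax(m, floor))
}

#' Median-polish summarisation of probes to transcript clusters
#'
#' Per cluster, fits the additive model
#' `value ~ overall + probe effect + sample effect` by iterative median sweeps
#' (rows first; tolerance 1e-4, at most 10 iterations) and reports
#' `overall + sample effect` as the cluster's log2 signal — the robust
#' summarisation step of RMA. Probes shared across clusters contribute to
#' each cluster's polish independently.
#'
#' @param m numeric matrix of probe-level log2 signals (probe ids as rownames).
#' @param mapping a [mapping_table()]; probes absent from `m` are ignored,
#'   clusters with zero probes in `m` are excluded with a warning.
#' @return numeric matrix, clusters x samples, log2 scale.
#' @export
median_polish_summarise <- function(m, mapping) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  if (!inherits(mapping, "mapping_table")) mapping <- mapping_table(mapping)
  assoc <- unique(mapping[, c("probe_id", "transcript_cluster_id")])
  assoc <- assoc[assoc$probe_id %in% rownames(m), ]
  clusters <- sort(unique(mapping$transcript_cluster_id))
  empty <- setdiff(clusters, assoc$transcript_cluster_id)
  if (length(empty)) {
    warning(length(empty), " cluster(s) had no probes in the matrix and were excluded")
    clusters <- setdiff(clusters, empty)
  }
  by_cluster <- split(assoc$probe_id, assoc$transcript_cluster_id)
  out <- matrix(NA_real_, nrow = length(clusters), ncol = ncol(m),
                dimnames = list(clusters, colnames(m)))
  for (cl in clusters) {
    x <- m[by_cluster[[cl]], , drop = FALSE]
    if (nrow(x) == 1L) {
      out[cl, ] <- x[1L, ]
    } else {
      # a bounded sweep count is part of the summarisation contract; hitting
      # the cap is expected on noisy clusters and not worth a warning
      fit <- withCallingHandlers(
        stats::medpolish(x, eps = 1e-4, maxiter = 10L, trace.iter = FALSE),
        warning = function(w) {
          if (grepl("did not converge", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
      out[cl, ] <- fit$overall + fit$col
    }
  }
  out
}

#' Mean batch adjustment of log2 signals
#'
#' Shifts each batch additively so that its grand mean equals the global grand
#' mean — the adjustment used to absorb minor batch effects after
#' normalisation. Within-batch variances are unchanged.
#'
#' @param m numeric matrix of log2 signals (samples in columns).
#' @param batches character vector of batch labels, one per column (or a named
#'   vector matched against colnames).
#' @return adjusted matrix.
#' @export
mean_batch_adjust <- function(m, batches) {
  stopifnot(is.matrix(m))
  if (!is.null(names(batches))) {
    missing <- setdiff(colnames(m), names(batches))
    if (length(missing))
      stop("no batch label for sample(s): ", paste(missing, collapse = ", "))
    batches <- batches[colnames(m)]
  }
  if (length(batches) != ncol(m))
    stop("need one batch label per sample")
  if (anyNA(batches)) stop("unknown (NA) batch label")
  grand <- mean(m)
  for (b in unique(batches)) {
    cols <- which(batches == b)
    m[, cols] <- m[, cols] + (grand - mean(m[, cols, drop = FALSE]))
  }
  m
}

#' Full preprocessing chain: probes to cluster-level log2 signals
#'
#' Quantile normalisation (linear scale), low-intensity floor + log2,
#' median-polish summarisation to transcript clusters, and optional mean batch
#' adjustment. Sample count and cluster universe are preserved.
#'
#' @param m probe-level linear-scale matrix (probe ids as rownames).
#' @param mapping a [mapping_table()].
#' @param batches optional batch labels for [mean_batch_adjust()].
#' @param floor linear-scale floor passed to [rma16_log()].
#' @return cluster-level log2 matrix.
#' @export
preprocess_pipeline <- function(m, mapping, batches = NULL, floor = 16) {
  m <- quantile_normalise(m)
  m <- rma16_log(m, floor = floor)
  m <- median_polish_summarise(m, mapping)
  if (!is.null(batches)) m <- mean_batch_adjust(m, batches)
  m
}
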