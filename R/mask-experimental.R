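#' Derive the experimental cross-hybridisation mask from host-only arrays
#'
#' Candidate clusters are those with the highest normalised mean signal on
#' host-only (NES) hybridisations of the human array: mean log2 signal per
#' cluster is computed across the NES replicates, clusters are ranked in
#' descending order, and the top `ceiling(top_fraction * N)` are selected,
#' extended to include any cluster tied with the cutoff value. The recorded
#' threshold is the minimum selected mean — the realised signal cutoff on this
#' data (the rank rule, not a fixed intensity, defines the mask).
#'
#' @param nes numeric matrix, cluster-level log2 signals of the host-only
#'   arrays (clusters in rows, NES replicates in columns).
#' @param top_fraction fraction of the cluster universe to select, in (0, 1)
#'   (default 0.01).
#' @return a [mask_set()] with provenance `"experimental"`; `parameters`
#'   records `top_fraction` and the realised `threshold` (min selected mean),
#'   `metadata` the universe and selection sizes.
#' @export
derive_experimental_mask <- function(nes, top_fraction = 0.01) {
  stopifnot(is.matrix(nes), !is.null(rownames(nes)))
  if (ncol(nes) < 1L) stop("need at least one NES sample")
  if (top_fraction <= 0 || top_fraction >= 1)
    stop("top_fraction must be in (0, 1)")
  means <- rowMeans(nes)
  n <- length(means)
  k <- ceiling(top_fraction * n)
  cutoff <- sort(means, decreasing = TRUE)[k]
  selected <- names(means)[means >= cutoff]
  if (length(selected) == n && n > k)
    warning("all clusters tied at the cutoff; entire universe selected")
  threshold <- unname(min(means[selected]))
  mask_set(selected, provenance = "experimental",
           parameters = list(top_fraction = top_fraction,
                             threshold = threshold),
           metadata = list(universe_size = n, k = k,
                           n_selected = length(selected)))
}
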