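#' A set of masked transcript clusters with provenance
#'
#' @param cluster_ids character vector of transcript cluster ids (deduplicated).
#' @param provenance one of `"insilico"`, `"experimental"`, `"combined"`.
#' @param parameters derivation parameters (rule config, signal threshold, ...).
#' @param metadata derivation metadata (stage counts, universe size, ...).
#' @return object of class `mask_set`.
#' @export
mask_set <- function(cluster_ids, provenance,
                     parameters = list(), metadata = list()) {
  provenance <- match.arg(provenance, c("insilico", "experimental", "combined"))
  structure(list(cluster_ids = sort(unique(as.character(cluster_ids))),
                 provenance = provenance,
                 parameters = parameters,
                 metadata = metadata),
            class = "mask_set")
}

#' @export
print.mask_set <- function(x, ...) {
  cat(sprintf("mask_set (%s): %d transcript clusters\n",
              x$provenance, length(x$cluster_ids)))
  invisible(x)
}

#' @export
length.mask_set <- function(x) length(x$cluster_ids)

#' Combine two masks by set union
#'
#' The combined mask is the union of the two cluster-id sets; metadata records
#' the input sizes, the intersection and the union so the inclusion-exclusion
#' identity |a| + |b| - |a n b| = |a u b| is always checkable.
#'
#' @param a,b [mask_set()] objects over the same cluster universe. If both
#'   record a universe size and they differ a warning is issued and the union
#'   taken anyway (ids are opaque).
#' @return a [mask_set()] with provenance `"combined"`.
#' @export
combine_masks <- function(a, b) {
  stopifnot(inherits(a, "mask_set"), inherits(b, "mask_set"))
  ua <- a$metadata$universe_size
  ub <- b$metadata$universe_size
  if (!is.null(ua) && !is.null(ub) && ua != ub)
    warning("masks record different cluster universes (", ua, " vs ", ub,
            "); taking the union anyway")
  ids <- union(a$cluster_ids, b$cluster_ids)
  inter <- intersect(a$cluster_ids, b$cluster_ids)
  stopifnot(length(ids) ==
              length(a$cluster_ids) + length(b$cluster_ids) - length(inter))
  mask_set(ids, provenance = "combined",
           parameters = list(a = a$parameters, b = b$parameters),
           metadata = list(n_a = length(a$cluster_ids),
                           n_b = length(b$cluster_ids),
                           n_intersection = length(inter),
                           n_union = length(ids),
                           universe_size = if (!is.null(ua)) ua else ub))
}

#' Apply a mask to a cluster-level expression matrix
#'
#' Removes the rows whose cluster id is in the mask; surviving row order is
#' preserved. Mask ids absent from the matrix are counted and reported in the
#' `n_absent` attribute, not fatal.
#'
#' @param m numeric matrix with cluster ids as rownames.
#' @param mask a [mask_set()].
#' @return the reduced matrix, with attributes `n_removed` and `n_absent`.
#' @export
apply_mask <- function(m, mask) {
  stopifnot(is.matrix(m), inherits(mask, "mask_set"))
  if (is.null(rownames(m))) stop("matrix must have cluster ids as rownames")
  hit <- rownames(m) %in% mask$cluster_ids
  absent <- setdiff(mask$cluster_ids, rownames(m))
  out <- m[!hit, , drop = FALSE]
  attr(out, "n_removed") <- sum(hit)
  attr(out, "n_absent") <- length(absent)
  if (length(absent))
    message(length(absent), " mask id(s) were absent from the matrix")
  out
}
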