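#' Three-tier probe/probeset/transcript-cluster mapping table
#'
#' Validates and deduplicates the association table the masks operate on.
#' Probes may belong to several probesets ("any probesets with which they are
#' associated"); probesets usually belong to one cluster but many-to-many is
#' tolerated.
#'
#' @param df data.frame with columns `probe_id`, `probeset_id`,
#'   `transcript_cluster_id`.
#' @return the deduplicated data.frame with class `mapping_table`.
#' @export
mapping_table <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("probe_id", "probeset_id", "transcript_cluster_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("mapping table is missing column(s): ", paste(miss, collapse = ", "))
  df <- unique(df[, need])
  if (nrow(df) == 0L) stop("mapping table is empty")
  rownames(df) <- NULL
  class(df) <- c("mapping_table", "data.frame")
  df
}

#' @export
print.mapping_table <- function(x, ...) {
  cat(sprintf("mapping_table: %d associations, %d probes, %d probesets, %d clusters\n",
              nrow(x), length(unique(x$probe_id)),
              length(unique(x$probeset_id)),
              length(unique(x$transcript_cluster_id))))
  invisible(x)
}

# One cluster id per probe (first association), named by probe id.
cluster_of_probe <- function(mapping) {
  u <- mapping[!duplicated(mapping$probe_id), ]
  stats::setNames(u$transcript_cluster_id, u$probe_id)
}

#' Rule configuration for the in silico mask
#'
#' @param probe_remaining_threshold a probeset is removed when the fraction of
#'   its original probes remaining is strictly below this value (default 0.5).
#' @param probeset_removed_threshold a cluster is masked when the fraction of
#'   its original probesets removed is at least this value (default 0.5).
#' @param max_mismatches hit criterion used upstream (default 1); recorded for
#'   provenance.
#' @return list of class `mask_rule_config`.
#' @export
mask_rule_config <- function(probe_remaining_threshold = 0.5,
                             probeset_removed_threshold = 0.5,
                             max_mismatches = 1L) {
  if (probe_remaining_threshold <= 0 || probe_remaining_threshold > 1 ||
      probeset_removed_threshold <= 0 || probeset_removed_threshold > 1)
    stop("mask rule thresholds must be in (0, 1]")
  structure(list(probe_remaining_threshold = probe_remaining_threshold,
                 probeset_removed_threshold = probeset_removed_threshold,
                 max_mismatches = as.integer(max_mismatches)),
            class = "mask_rule_config")
}

#' Derive the in silico cross-hybridisation mask
#'
#' Propagates probe-level host-genome hits up the hierarchy:
#' \enumerate{
#'   \item every hit probe is removed from every probeset containing it;
#'   \item a probeset is removed from its cluster(s) when strictly fewer than
#'     `probe_remaining_threshold` of its original probes remain;
#'   \item a cluster is masked when at least `probeset_removed_threshold` of
#'     its original probesets have been removed.
#' }
#' Denominators are always the original association counts from the mapping
#' table. Boundary semantics are literal: exactly 50% of probes remaining
#' keeps the probeset; exactly 50% of probesets removed masks the cluster.
#'
#' @param hit_probe_ids character vector of probe ids that hit the host genome
#'   (e.g. `unique(hits$probe_id)` from [match_probes()]).
#' @param mapping a [mapping_table()].
#' @param rules a [mask_rule_config()].
#' @return a [mask_set()] with provenance `"insilico"`; `metadata` records the
#'   counts at each filtering stage.
#' @export
derive_insilico_mask <- function(hit_probe_ids, mapping,
                                 rules = mask_rule_config()) {
  if (!inherits(mapping, "mapping_table")) mapping <- mapping_table(mapping)
  stopifnot(inherits(rules, "mask_rule_config"))
  hit_probe_ids <- unique(as.character(hit_probe_ids))
  unknown <- setdiff(hit_probe_ids, mapping$probe_id)
  if (length(unknown))
    stop("hit probe id(s) absent from mapping table: ",
         paste(utils::head(unknown, 10L), collapse = ", "),
         if (length(unknown) > 10L) ", ...")

  pp <- unique(mapping[, c("probe_id", "probeset_id")])
  ps_orig <- table(pp$probeset_id)
  hit_pp <- pp[pp$probe_id %in% hit_probe_ids, ]
  ps_hit <- table(factor(hit_pp$probeset_id, levels = names(ps_orig)))
  remaining_frac <- as.numeric(ps_orig - ps_hit) / as.numeric(ps_orig)
  removed_ps <- names(ps_orig)[remaining_frac < rules$probe_remaining_threshold]

  pc <- unique(mapping[, c("probeset_id", "transcript_cluster_id")])
  cl_orig <- table(pc$transcript_cluster_id)
  rem_pc <- pc[pc$probeset_id %in% removed_ps, ]
  cl_removed <- table(factor(rem_pc$transcript_cluster_id,
                             levels = names(cl_orig)))
  removed_frac <- as.numeric(cl_removed) / as.numeric(cl_orig)
  masked <- names(cl_orig)[removed_frac >= rules$probeset_removed_threshold]

  mask_set(masked, provenance = "insilico", parameters = rules,
           metadata = list(
             n_hit_probes = length(hit_probe_ids),
             n_probesets_removed = length(removed_ps),
             n_clusters_masked = length(masked),
             universe_size = length(cl_orig)))
}
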