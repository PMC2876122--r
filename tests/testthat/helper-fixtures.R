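# Shared fixtures built in code.

random_genome <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  c(g = paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""))
}

# A hand-built mapping: clusters with a configurable number of probesets and
# probes, ids like C1, C1_PS1, C1_PS1_P1.
toy_mapping <- function(n_clusters = 2, probesets = 2, probes = 4) {
  rows <- expand.grid(pr = seq_len(probes), ps = seq_len(probesets),
                      cl = seq_len(n_clusters))
  mapping_table(data.frame(
    probe_id = sprintf("C%d_PS%d_P%d", rows$cl, rows$ps, rows$pr),
    probeset_id = sprintf("C%d_PS%d", rows$cl, rows$ps),
    transcript_cluster_id = sprintf("C%d", rows$cl),
    stringsAsFactors = FALSE))
}

# Small but complete simulated study used by several suites.
small_study <- function(seed = 7, n_clusters = 40, frac = 0.1,
                        genome_length = 6000) {
  simulate_mixture_study(simulation_config(
    n_clusters = n_clusters, frac_homologous_clusters = frac,
    genome_length = genome_length, seed = seed))
}

expect_same_hits <- function(a, b) {
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
}
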