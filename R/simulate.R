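#' Configuration for the mixed-species simulation
#'
#' Defines a miniature xenograft world: a host genome, an array design whose
#' probes are grouped into probesets and transcript clusters, a fraction of
#' clusters whose probes are planted from the host genome (and hence truly
#' susceptible to cross-species hybridisation), and graded human/host cell
#' mixtures hybridised with replication.
#'
#' The mixture design mirrors the validation experiment: pure human
#' hybridisations plus 95% and 90% human cell mixtures
#' (`mixture_fractions = c(1, 0.95, 0.90)`), and host-only (`NES`, f = 0)
#' hybridisations used to derive the experimental mask.
#'
#' Contaminated clusters get `ceiling(planted_probeset_fraction *
#' probesets_per_cluster)` probesets whose probes are all copied from genome
#' windows (with exactly `homolog_mismatches` substitutions each), which
#' guarantees the cluster satisfies the in silico mask rule by construction.
#' A planted probe's host affinity is `host_affinity_fold` times its cluster's
#' human signal; every probe additionally sees a small constant optical
#' background on the host side so host-only hybridisations sit at background
#' rather than zero.
#'
#' @param n_clusters number of transcript clusters.
#' @param probesets_per_cluster probesets per cluster (default 4).
#' @param probes_per_probeset probes per probeset (default 4).
#' @param probe_length probe length in bases (default 25; must be >= 13 so the
#'   matcher can seed from two tiles).
#' @param frac_homologous_clusters fraction of clusters planted from the host
#'   genome, in \[0, 1\].
#' @param homolog_mismatches substitutions injected into each planted probe
#'   (0 or 1).
#' @param genome_length host genome length in bases.
#' @param mixture_fractions human cell fractions f to simulate
#'   (default `c(1, 0.95, 0.90)`).
#' @param replicates_per_mixture arrays per mixture (default 3).
#' @param nes_replicates host-only (f = 0) arrays (default 3).
#' @param noise_sd multiplicative log-normal noise SD on the log2 scale
#'   (default 0.1).
#' @param planted_probeset_fraction fraction of a contaminated cluster's
#'   probesets that are planted (default 0.75; must be >= 0.5 so the cluster is
#'   masked by construction).
#' @param host_affinity_fold host affinity of a planted probe relative to its
#'   cluster's human signal (default 20). Planted probes are at most one
#'   substitution from the host genome, i.e. essentially perfect host probes,
#'   so an affinity well above the human-driven signal is the realistic
#'   regime; the default makes contamination a 2-fold (|M| >= 1) effect at a
#'   90% human mixture, since the probe-level shift there is
#'   `log2(0.9 + 0.1 * fold)`.
#' @param human_signal_log2_mean,human_signal_log2_sd log2-normal parameters of
#'   per-cluster human signal (defaults 8 and 1.5).
#' @param background_signal constant linear-scale optical background on the
#'   host side (default 30).
#' @param seed integer seed; the whole world is reproducible given the config.
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_clusters = 100L,
                              probesets_per_cluster = 4L,
                              probes_per_probeset = 4L,
                              probe_length = 25L,
                              frac_homologous_clusters = 0.05,
                              homolog_mismatches = 1L,
                              genome_length = 20000L,
                              mixture_fractions = c(1, 0.95, 0.90),
                              replicates_per_mixture = 3L,
                              nes_replicates = 3L,
                              noise_sd = 0.1,
                              planted_probeset_fraction = 0.75,
                              host_affinity_fold = 20,
                              human_signal_log2_mean = 8,
                              human_signal_log2_sd = 1.5,
                              background_signal = 30,
                              seed = 1L) {
  cfg <- list(n_clusters = as.integer(n_clusters),
              probesets_per_cluster = as.integer(probesets_per_cluster),
              probes_per_probeset = as.integer(probes_per_probeset),
              probe_length = as.integer(probe_length),
              frac_homologous_clusters = frac_homologous_clusters,
              homolog_mismatches = as.integer(homolog_mismatches),
              genome_length = as.integer(genome_length),
              mixture_fractions = mixture_fractions,
              replicates_per_mixture = as.integer(replicates_per_mixture),
              nes_replicates = as.integer(nes_replicates),
              noise_sd = noise_sd,
              planted_probeset_fraction = planted_probeset_fraction,
              host_affinity_fold = host_affinity_fold,
              human_signal_log2_mean = human_signal_log2_mean,
              human_signal_log2_sd = human_signal_log2_sd,
              background_signal = background_signal,
              seed = as.integer(seed))
  with(cfg, {
    if (n_clusters < 1L || probesets_per_cluster < 1L ||
        probes_per_probeset < 1L || replicates_per_mixture < 1L ||
        nes_replicates < 1L)
      stop("invalid config: all counts must be >= 1")
    if (probe_length < 13L)
      stop("invalid config: probe_length must be >= 13 (two seed tiles)")
    if (frac_homologous_clusters < 0 || frac_homologous_clusters > 1)
      stop("invalid config: frac_homologous_clusters must be in [0, 1]")
    if (any(mixture_fractions < 0 | mixture_fractions > 1))
      stop("invalid config: mixture fractions must be in [0, 1]")
    if (!homolog_mismatches %in% c(0L, 1L))
      stop("invalid config: homolog_mismatches must be 0 or 1")
    if (genome_length < probe_length)
      stop("invalid config: genome_length must be >= probe_length")
    if (planted_probeset_fraction < 0.5 || planted_probeset_fraction > 1)
      stop("invalid config: planted_probeset_fraction must be in [0.5, 1]")
    if (noise_sd < 0) stop("invalid config: noise_sd must be >= 0")
  })
  structure(cfg, class = "simulation_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a random host genome
#'
#' Uniform-composition uppercase sequence over A/C/G/T, reproducible for a
#' fixed config seed.
#'
#' @param config a [simulation_config()].
#' @return named character vector of length 1 (id `"host_chr"`).
#' @export
generate_host_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  c(host_chr = random_dna(config$genome_length))
}

inject_mismatches <- function(seq, k) {
  if (k == 0L) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  pos <- sample(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}

#' Generate an array design with planted host-homologous probes
#'
#' Builds the three-tier probe/probeset/transcript-cluster hierarchy. A fixed
#' number of clusters (`round(frac_homologous_clusters * n_clusters)`) are
#' contaminated: a majority of their probesets consist of probes copied from
#' host genome windows (with exactly `homolog_mismatches` substitutions), so
#' each such cluster is guaranteed to satisfy the in silico mask rule. All
#' other probes are random sequences rejection-sampled to have no placement on
#' the genome within one mismatch, giving a clean negative set.
#'
#' @param config a [simulation_config()].
#' @param genome the genome from [generate_host_genome()] with the same config.
#' @return list with elements `probes` (probe table), `mapping`
#'   ([mapping_table()]) and `truth` (ground truth: `contaminated_clusters`,
#'   per-probe `host_affinity`, per-cluster linear-scale `human_signal`).
#' @export
generate_array_design <- function(config, genome) {
  stopifnot(inherits(config, "simulation_config"))
  genome <- as_genome(genome)
  set.seed(config$seed + 1L)
  n_cl <- config$n_clusters
  n_ps <- config$probesets_per_cluster
  n_pr <- config$probes_per_probeset
  L <- config$probe_length
  glen <- nchar(genome[[1L]])
  idx <- build_seed_index(genome, tile_size = min(12L, L %/% 2L),
                          step_size = 1L)

  n_contam <- round(config$frac_homologous_clusters * n_cl)
  contam <- if (n_contam > 0L) sort(sample(n_cl, n_contam)) else integer()
  n_planted_ps <- ceiling(config$planted_probeset_fraction * n_ps)

  cluster_ids <- sprintf("TC%05d", seq_len(n_cl))
  probe_id <- probeset_id <- probe_cluster <- seq_chr <- character()
  planted <- logical()
  n_windows <- glen - L + 1L
  if (n_contam > 0L && n_windows < 1L)
    stop("generation error: genome too short to place homologous probes")

  rows <- vector("list", n_cl)
  for (ci in seq_len(n_cl)) {
    is_contam <- ci %in% contam
    pid <- psid <- cl <- sq <- character(n_ps * n_pr)
    pl <- logical(n_ps * n_pr)
    k <- 0L
    for (psi in seq_len(n_ps)) {
      plant_ps <- is_contam && psi <= n_planted_ps
      for (pri in seq_len(n_pr)) {
        k <- k + 1L
        pid[k] <- sprintf("P%05d_%d_%d", ci, psi, pri)
        psid[k] <- sprintf("PS%05d_%d", ci, psi)
        cl[k] <- cluster_ids[ci]
        pl[k] <- plant_ps
        if (plant_ps) {
          w <- sample(n_windows, 1L) - 1L
          sq[k] <- inject_mismatches(substr(genome[[1L]], w + 1L, w + L),
                                     config$homolog_mismatches)
        } else {
          ok <- FALSE
          for (try in seq_len(100L)) {
            cand <- random_dna(L)
            if (nrow(find_hits(cand, idx, genome, max_mismatches = 1L)) == 0L) {
              sq[k] <- cand; ok <- TRUE; break
            }
          }
          if (!ok) stop("generation error: could not sample a probe with no ",
                        "near-match on the genome")
        }
      }
    }
    rows[[ci]] <- list(pid, psid, cl, sq, pl)
  }
  probe_id <- unlist(lapply(rows, `[[`, 1L))
  probeset_id <- unlist(lapply(rows, `[[`, 2L))
  probe_cluster <- unlist(lapply(rows, `[[`, 3L))
  seq_chr <- unlist(lapply(rows, `[[`, 4L))
  planted <- unlist(lapply(rows, `[[`, 5L))

  human_signal <- 2 ^ stats::rnorm(n_cl, config$human_signal_log2_mean,
                                   config$human_signal_log2_sd)
  names(human_signal) <- cluster_ids
  host_affinity <- ifelse(planted,
                          config$host_affinity_fold *
                            human_signal[probe_cluster], 0)
  names(host_affinity) <- probe_id

  probes <- data.frame(probe_id = probe_id, sequence = seq_chr,
                       stringsAsFactors = FALSE)
  mapping <- mapping_table(data.frame(probe_id = probe_id,
                                      probeset_id = probeset_id,
                                      transcript_cluster_id = probe_cluster,
                                      stringsAsFactors = FALSE))
  truth <- list(contaminated_clusters = cluster_ids[contam],
                host_affinity = host_affinity,
                human_signal = human_signal)
  list(probes = probes, mapping = mapping, truth = truth)
}

#' Simulate probe-level intensities for a human/host cell mixture
#'
#' Linear-scale probe intensity is
#' `f * human_signal(cluster) + (1 - f) * (host_affinity(probe) + background)`,
#' then multiplied by log-normal noise with SD `noise_sd` on the log2 scale.
#' Host affinity is nonzero only for planted probes, so a host-only (f = 0)
#' hybridisation puts every non-planted probe at the optical background.
#'
#' @param design the design list from [generate_array_design()].
#' @param truth ground truth (defaults to `design$truth`).
#' @param f human cell fraction in \[0, 1\] (f = 0 is a host-only/NES array).
#' @param n_reps number of replicate arrays.
#' @param seed integer seed for the noise draws.
#' @param noise_sd log2-scale noise SD.
#' @param background_signal linear-scale optical background.
#' @param label column-name prefix; default `"NES"` when f = 0, otherwise
#'   e.g. `"ALL.95"`.
#' @return numeric matrix (probes x replicates), linear scale, columns
#'   `label_1`, `label_2`, ...
#' @export
simulate_expression <- function(design, truth = design$truth, f, n_reps,
                                seed = 1L, noise_sd = 0.1,
                                background_signal = 30,
                                label = NULL) {
  if (f < 0 || f > 1) stop("invalid config: f must be in [0, 1]")
  stopifnot(n_reps >= 1L)
  set.seed(seed)
  mapping <- design$mapping
  probe_cluster <- cluster_of_probe(mapping)
  probe_ids <- names(probe_cluster)
  mu <- f * truth$human_signal[probe_cluster] +
    (1 - f) * (truth$host_affinity[probe_ids] + background_signal)
  if (is.null(label)) label <- if (f == 0) "NES" else sprintf("ALL.%g", 100 * f)
  m <- matrix(rep(mu, n_reps), ncol = n_reps,
              dimnames = list(probe_ids, paste(label, seq_len(n_reps),
                                               sep = "_")))
  if (noise_sd > 0)
    m <- m * 2 ^ matrix(stats::rnorm(length(m), 0, noise_sd), nrow = nrow(m))
  m
}

#' Simulate a full mixing study
#'
#' Generates the genome, design and ground truth, then probe-level intensity
#' matrices for every mixture fraction in the config plus host-only (NES)
#' arrays, column-labelled by mixture and replicate.
#'
#' @param config a [simulation_config()].
#' @return list: `genome`, `probes`, `mapping`, `truth`, `intensities` (one
#'   linear-scale probe matrix, all samples), `groups` (named character vector
#'   mapping sample id to group label).
#' @export
simulate_mixture_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  genome <- generate_host_genome(config)
  design <- generate_array_design(config, genome)
  mats <- list()
  for (i in seq_along(config$mixture_fractions)) {
    f <- config$mixture_fractions[i]
    mats[[length(mats) + 1L]] <- simulate_expression(
      design, f = f, n_reps = config$replicates_per_mixture,
      seed = config$seed + 100L + i, noise_sd = config$noise_sd,
      background_signal = config$background_signal)
  }
  mats[[length(mats) + 1L]] <- simulate_expression(
    design, f = 0, n_reps = config$nes_replicates,
    seed = config$seed + 200L, noise_sd = config$noise_sd,
    background_signal = config$background_signal)
  intensities <- do.call(cbind, mats)
  groups <- sub("_[0-9]+$", "", colnames(intensities))
  names(groups) <- colnames(intensities)
  list(genome = genome, probes = design$probes, mapping = design$mapping,
       truth = design$truth, intensities = intensities, groups = groups)
}
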