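test_that("config invariants are enforced", {
  expect_error(simulation_config(n_clusters = 0), "counts")
  expect_error(simulation_config(probe_length = 12), "probe_length")
  expect_error(simulation_config(frac_homologous_clusters = 1.2), "\\[0, 1\\]")
  expect_error(simulation_config(genome_length = 10, probe_length = 25),
               "genome_length")
  expect_error(simulation_config(homolog_mismatches = 2), "0 or 1")
  expect_error(simulation_config(mixture_fractions = c(1, -0.1)), "fractions")
})

test_that("genome generation is seeded-deterministic with uniform composition", {
  cfg <- simulation_config(n_clusters = 5, genome_length = 2000, seed = 1)
  g1 <- generate_host_genome(cfg)
  g2 <- generate_host_genome(cfg)
  expect_identical(g1, g2)
  expect_match(unname(g1), "^[ACGT]+$")
  expect_equal(nchar(g1[[1]]), 2000L)

  # boundary: genome of exactly one probe length
  cfg25 <- simulation_config(n_clusters = 1, genome_length = 25, seed = 2,
                             frac_homologous_clusters = 0)
  expect_equal(nchar(generate_host_genome(cfg25)[[1]]), 25L)

  # composition of a 100 kb genome is compatible with uniform at alpha = 0.001
  big <- generate_host_genome(simulation_config(n_clusters = 1,
                                                genome_length = 100000L,
                                                seed = 3))
  counts <- table(strsplit(big[[1]], "")[[1]])
  expect_gt(stats::chisq.test(counts, p = rep(0.25, 4))$p.value, 0.001)
})

test_that("design generation plants the configured number of contaminated clusters", {
  cfg0 <- simulation_config(n_clusters = 30, frac_homologous_clusters = 0,
                            genome_length = 4000, seed = 5)
  d0 <- generate_array_design(cfg0, generate_host_genome(cfg0))
  expect_length(d0$truth$contaminated_clusters, 0L)

  cfg <- simulation_config(n_clusters = 100, frac_homologous_clusters = 0.05,
                           genome_length = 20000, seed = 6)
  d <- generate_array_design(cfg, generate_host_genome(cfg))
  expect_length(d$truth$contaminated_clusters, 5L)
  expect_true(all(d$truth$contaminated_clusters %in%
                    d$mapping$transcript_cluster_id))
  # identical config regenerates the identical design
  d2 <- generate_array_design(cfg, generate_host_genome(cfg))
  expect_identical(d, d2)
})

test_that("planted probes hit the genome and rejection-sampled probes never do", {
  cfg <- simulation_config(n_clusters = 12, frac_homologous_clusters = 0.25,
                           genome_length = 3000, seed = 8,
                           homolog_mismatches = 1)
  genome <- generate_host_genome(cfg)
  d <- generate_array_design(cfg, genome)
  planted <- names(d$truth$host_affinity)[d$truth$host_affinity > 0]
  for (i in seq_len(nrow(d$probes))) {
    n_hits <- nrow(brute_force_hits(d$probes$sequence[i], genome))
    if (d$probes$probe_id[i] %in% planted) {
      expect_gte(n_hits, 1L)
    } else {
      expect_equal(n_hits, 0L)
    }
  }
  # planting respects the hierarchy: affinity is constant within a probeset
  by_ps <- split(d$truth$host_affinity[d$mapping$probe_id],
                 d$mapping$probeset_id)
  expect_true(all(vapply(by_ps, function(x) length(unique(x > 0)) == 1L, TRUE)))
})

test_that("expression model: pure human is exact, host-only sits at background", {
  st_cfg <- simulation_config(n_clusters = 10, frac_homologous_clusters = 0.2,
                              genome_length = 3000, seed = 9)
  genome <- generate_host_genome(st_cfg)
  d <- generate_array_design(st_cfg, genome)
  pure <- simulate_expression(d, f = 1, n_reps = 2, seed = 1, noise_sd = 0)
  cl_of <- d$mapping$transcript_cluster_id[match(rownames(pure),
                                                 d$mapping$probe_id)]
  expect_equal(unname(pure[, 1]), unname(d$truth$human_signal[cl_of]))
  expect_equal(pure[, 1], pure[, 2])

  cfg_clean <- simulation_config(n_clusters = 10, frac_homologous_clusters = 0,
                                 genome_length = 3000, seed = 10)
  g2 <- generate_host_genome(cfg_clean)
  d2 <- generate_array_design(cfg_clean, g2)
  host <- simulate_expression(d2, f = 0, n_reps = 1, seed = 1, noise_sd = 0,
                              background_signal = 30)
  expect_true(all(host == 30))
  expect_error(simulate_expression(d2, f = 1.5, n_reps = 1), "\\[0, 1\\]")
})

test_that("Monte-Carlo mean of a noisy planted probe matches the mixture model", {
  cfg <- simulation_config(n_clusters = 6, frac_homologous_clusters = 0.5,
                           genome_length = 3000, seed = 12)
  genome <- generate_host_genome(cfg)
  d <- generate_array_design(cfg, genome)
  planted <- names(d$truth$host_affinity)[d$truth$host_affinity > 0][1]
  f <- 0.9
  m <- simulate_expression(d, f = f, n_reps = 100, seed = 13, noise_sd = 0.1,
                           background_signal = 30)
  cl <- d$mapping$transcript_cluster_id[match(planted, d$mapping$probe_id)]
  expected <- f * d$truth$human_signal[[cl]] +
    (1 - f) * (d$truth$host_affinity[[planted]] + 30)
  obs <- m[planted, ]
  se <- stats::sd(obs) / sqrt(length(obs))
  expect_lt(abs(mean(obs) - expected), 2 * se + 0.01 * expected)
})

test_that("contamination is monotone in host fraction when affinity exceeds signal", {
  cfg <- simulation_config(n_clusters = 6, frac_homologous_clusters = 0.5,
                           genome_length = 3000, seed = 14,
                           host_affinity_fold = 10)
  genome <- generate_host_genome(cfg)
  d <- generate_array_design(cfg, genome)
  planted <- names(d$truth$host_affinity)[d$truth$host_affinity > 0]
  ms <- lapply(c(1, 0.95, 0.90), function(f)
    simulate_expression(d, f = f, n_reps = 1, seed = 1, noise_sd = 0))
  expect_true(all(ms[[3]][planted, 1] >= ms[[2]][planted, 1]))
  expect_true(all(ms[[2]][planted, 1] >= ms[[1]][planted, 1]))
})

test_that("a full study is reproducible and labelled by mixture and replicate", {
  st1 <- small_study(seed = 15, n_clusters = 10, genome_length = 3000)
  st2 <- small_study(seed = 15, n_clusters = 10, genome_length = 3000)
  expect_identical(st1$intensities, st2$intensities)
  expect_setequal(unique(st1$groups), c("ALL.100", "ALL.95", "ALL.90", "NES"))
  expect_equal(sum(st1$groups == "NES"), 3L)
  expect_equal(ncol(st1$intensities), 12L)
})
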