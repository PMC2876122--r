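sim_log2_matrix <- function(n_clusters, labels, seed = 1) {
  set.seed(seed)
  cols <- unlist(lapply(seq_along(labels), function(i)
    paste0(labels[i], "_", i)))
  m <- matrix(rnorm(n_clusters * length(labels), mean = 7, sd = 1),
              ncol = length(labels),
              dimnames = list(sprintf("c%04d", seq_len(n_clusters)), cols))
  list(m = m, groups = setNames(labels, cols))
}

test_that("pearson summary counts pairs combinatorially (4v4 and 3v8)", {
  x <- sim_log2_matrix(100, rep(c("BM", "SP"), each = 4), seed = 201)
  ps <- pearson_summary(x$m, x$groups)
  expect_true(isSymmetric(ps$correlations))
  expect_equal(unname(diag(ps$correlations)), rep(1, 8))
  s <- ps$summaries
  get_n <- function(a, b) s$n[s$group_a == a & s$group_b == b]
  expect_equal(get_n("BM", "BM"), 6L)
  expect_equal(get_n("SP", "SP"), 6L)
  expect_equal(get_n("BM", "SP"), 16L)
  expect_equal(s$se, s$sd / sqrt(s$n))

  y <- sim_log2_matrix(100, rep(c("ALL.90", "ALL.100"), c(3, 8)), seed = 202)
  ps2 <- pearson_summary(y$m, y$groups)
  s2 <- ps2$summaries
  expect_equal(s2$n[s2$group_a == "ALL.90" & s2$group_b == "ALL.100"], 24L)
  expect_equal(s2$n[s2$group_a == "ALL.90" & s2$group_b == "ALL.90"], 3L)
})

test_that("pearson edge cases: duplicated sample, anticorrelation, zero variance", {
  v <- c(1, 3, 2, 5, 4)
  m <- cbind(a = v, b = v, c = -v)
  rownames(m) <- paste0("r", 1:5)
  ps <- pearson_summary(m, setNames(c("g1", "g1", "g2"), c("a", "b", "c")))
  expect_equal(ps$correlations["a", "b"], 1)
  expect_equal(ps$correlations["a", "c"], -1)
  m2 <- cbind(a = v, b = rep(2, 5))
  expect_error(pearson_summary(m2, c("g", "g")), "zero-variance.*b")
})

test_that("MvA records and the 2-fold outlier rule (|M| >= 1, inclusive)", {
  means <- setNames(rnorm(50, 7), paste0("c", 1:50))
  same <- mva(means, means)
  expect_true(all(same$records$M == 0))
  expect_equal(same$n_outliers, 0L)
  expect_equal(same$records$A, unname(means))

  shifted <- means
  shifted["c7"] <- shifted["c7"] + 1 # exactly 2-fold: boundary counts
  mv <- mva(shifted, means)
  expect_equal(mv$n_outliers, 1L)
  expect_equal(mv$outlier_ids, "c7")
  expect_equal(mv$records$M[mv$records$cluster_id == "c7"], 1)
  expect_error(mva(means, means[-1]), "universes differ")
})

test_that("ranked MSD: zero iff identical, constant offset gives its square", {
  ref <- setNames(sort(rnorm(30, 7), decreasing = TRUE), paste0("c", 1:30))
  expect_equal(msd_ranked(ref, ref)$msd, 0)
  expect_equal(msd_ranked(ref, ref + 1)$msd, 1)
  expect_equal(msd_ranked(ref, ref - 0.5)$msd, 0.25)
  # invariant to cluster order in the input
  perm <- sample(names(ref))
  expect_equal(msd_ranked(ref[perm], (ref + 1)[rev(perm)])$msd, 1)
  # ranked output is in descending reference order
  r <- msd_ranked(ref[perm], ref[perm])$ranked
  expect_equal(r$reference, sort(ref, decreasing = TRUE), ignore_attr = TRUE)
  expect_error(msd_ranked(ref, ref[-1]), "universes differ")
})

test_that("signal histogram conserves counts and separates host from human", {
  x <- sim_log2_matrix(200, rep(c("ALL.100", "NES"), each = 3), seed = 203)
  x$m[, 4:6] <- x$m[, 4:6] - 2 # host-only arrays sit lower
  h <- signal_histogram(x$m, x$groups, bins = 20)
  expect_equal(unname(colSums(h$counts)), c(200, 200))
  expect_length(h$breaks, 21L)
  # NES mass above the human median is smaller than the ALL.100 mass
  mids <- (h$breaks[-1] + h$breaks[-21]) / 2
  cut <- stats::median(rowMeans(x$m[, 1:3]))
  expect_lt(sum(h$counts[mids > cut, "NES"]),
            sum(h$counts[mids > cut, "ALL.100"]))
  expect_error(signal_histogram(x$m[0, , drop = FALSE], x$groups), "empty")
})

test_that("single-cluster histogram has one occupied bin", {
  m <- matrix(c(5, 5.1), nrow = 1, dimnames = list("c1", c("a", "b")))
  h <- signal_histogram(m, setNames(c("g1", "g2"), c("a", "b")), bins = 5)
  expect_equal(sum(h$counts[, "g1"] > 0), 1L)
})

test_that("BH adjustment: hand example, caps, and input validation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.27, 0.6)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("moderated t matches limma's empirical Bayes on a random fixture", {
  x <- sim_log2_matrix(300, rep(c("g1", "g2"), each = 4), seed = 205)
  # add real differences to a subset so the variance spread is non-trivial
  x$m[1:20, 1:4] <- x$m[1:20, 1:4] + 1.5
  fit <- moderated_t_test(x$m, x$groups)

  f <- factor(x$groups, levels = c("g2", "g1"))
  design <- stats::model.matrix(~f)
  lfit <- limma::eBayes(limma::lmFit(x$m, design))
  expect_equal(fit$d0, lfit$df.prior, tolerance = 1e-6)
  expect_equal(fit$s02, lfit$s2.prior, tolerance = 1e-6)
  expect_equal(fit$table$logFC, unname(lfit$coefficients[, 2]),
               tolerance = 1e-10)
  expect_equal(fit$table$t, unname(lfit$t[, 2]), tolerance = 1e-8)
  expect_equal(fit$table$p, unname(lfit$p.value[, 2]), tolerance = 1e-8)
})

test_that("moderated t limiting cases bracket the ordinary t", {
  x <- sim_log2_matrix(200, rep(c("g1", "g2"), each = 4), seed = 207)
  fit <- moderated_t_test(x$m, x$groups)
  # hand-computed ordinary pooled t for one cluster
  v <- x$m[5, ]
  g1 <- v[1:4]; g2 <- v[5:8]
  sp2 <- (sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)) / 6
  t_ord <- (mean(g1) - mean(g2)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  # the moderated statistic shrinks toward the prior: it lies between the
  # ordinary t and the t computed with the prior variance alone
  t_prior <- (mean(g1) - mean(g2)) / sqrt(fit$s02 * (1 / 4 + 1 / 4))
  t_mod <- fit$table$t[5]
  expect_true((t_mod - t_ord) * (t_prior - t_ord) >= 0)
  expect_lte(abs(t_mod), max(abs(t_ord), abs(t_prior)) + 1e-12)

  # d0 -> Inf in effect: constant within-cluster variance gives equal
  # posterior variances for all clusters
  set.seed(208)
  base <- rnorm(8)
  m_const <- t(sapply(1:50, function(i) base + rnorm(1, sd = 3)))
  dimnames(m_const) <- list(paste0("c", 1:50), names(x$groups))
  fit_const <- moderated_t_test(m_const, x$groups)
  expect_equal(fit_const$d0, Inf)
})

test_that("moderated t requires two groups with replication", {
  x <- sim_log2_matrix(10, c("g1", "g1", "g2"), seed = 209)
  expect_error(moderated_t_test(x$m, x$groups), "at least 2 samples")
  y <- sim_log2_matrix(10, rep("g1", 4), seed = 210)
  expect_error(moderated_t_test(y$m, y$groups), "two groups")
})
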