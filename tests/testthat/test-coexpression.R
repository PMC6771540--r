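test_that("correlation matrices are Pearson with guarded degeneracies", {
  m <- rbind(g1 = c(1, 2, 3, 4),
             g2 = c(-1, -2, -3, -4),
             g3 = c(2, 1, 4, 3),
             flat = c(5, 5, 5, 5))
  expect_warning(r <- correlation_matrix(m), "zero-variance")
  expect_equal(r["g1", "g1"], 1)
  expect_equal(r["g1", "g2"], -1)
  # direct covariance/sd oracle
  oracle <- cov(m["g1", ], m["g3", ]) / (sd(m["g1", ]) * sd(m["g3", ]))
  expect_equal(r["g1", "g3"], oracle)
  expect_equal(unname(r["flat", "g1"]), 0)
  expect_equal(r, t(r))
  expect_error(correlation_matrix(m[, 1:2]), "3 samples")
})

test_that("soft thresholding raises correlations to the power beta", {
  r <- matrix(c(1, 0.8, 0, 0.8, 1, -0.5, 0, -0.5, 1), 3)
  a <- soft_threshold_adjacency(r, beta = 16)
  expect_equal(diag(a), rep(0, 3))
  expect_equal(a[1, 2], 0.8^16)
  expect_equal(a[1, 2], 0.0281474977, tolerance = 1e-8)
  expect_equal(a[1, 3], 0)
  expect_equal(a[2, 3], 0.5^16)  # unsigned: sign is dropped
  s <- soft_threshold_adjacency(r, beta = 2, network_type = "signed")
  expect_equal(s[2, 3], ((1 - 0.5) / 2)^2)
})

test_that("TOM matches hand-computed values and the brute-force oracle", {
  # two nodes, full adjacency: (0 + 1) / (1 + 1 - 1) = 1
  a2 <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(topological_overlap(a2)$similarity[1, 2], 1)

  # all-zero adjacency: no overlap off-diagonal
  z <- matrix(0, 3, 3)
  expect_equal(topological_overlap(z)$similarity, diag(3))

  # three nodes, uniform 0.5: (0.25 + 0.5) / (1 + 1 - 0.5) = 0.5
  u <- matrix(0.5, 3, 3); diag(u) <- 0
  expect_equal(topological_overlap(u)$similarity[1, 2], 0.5)

  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(3:20, 1)
    a <- matrix(runif(n * n), n)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    tom <- topological_overlap(a)
    expect_equal(tom$similarity, brute_force_tom(a), tolerance = 1e-12)
    expect_true(all(tom$similarity >= 0 & tom$similarity <= 1 + 1e-12))
    expect_equal(tom$similarity, t(tom$similarity))
    expect_equal(tom$dissimilarity, 1 - tom$similarity)
  }
})

test_that("average linkage merges at mean inter-cluster dissimilarity", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("a", "b"),
                                                     c("a", "b")))
  hc <- average_linkage_cluster(d2)
  expect_equal(hc$height, 0.4)

  # two tight blocks: the last merge height is the mean inter-block value
  set.seed(3)
  n <- 6
  d <- matrix(0, n, n, dimnames = list(paste0("g", 1:n), paste0("g", 1:n)))
  inter <- matrix(runif(9, 0.8, 1), 3)
  d[1:3, 4:6] <- inter; d[4:6, 1:3] <- t(inter)
  within <- 0.05
  d[1:3, 1:3] <- within; d[4:6, 4:6] <- within
  diag(d) <- 0
  hc <- average_linkage_cluster(d)
  expect_equal(max(hc$height), mean(inter))

  # permuting the input yields the same cluster structure
  perm <- sample(n)
  hc_p <- average_linkage_cluster(d[perm, perm])
  expect_equal(adjusted_rand_index(cutree(hc, k = 2)[rownames(d)],
                                   cutree(hc_p, k = 2)[rownames(d)]), 1)
  expect_error(average_linkage_cluster(matrix(c(0, NA, NA, 0), 2)), "finite")
})

test_that("tree cutting forms size-filtered, size-ordered modules", {
  set.seed(4)
  block <- function(n, center) matrix(rnorm(n * 10, center), n)
  m <- rbind(block(50, 0) + rep(rnorm(10, sd = 3), each = 50),
             block(50, 0) + rep(rnorm(10, sd = 3), each = 50))
  rownames(m) <- paste0("g", 1:100)
  # construct a clean two-block dissimilarity directly
  d <- matrix(1, 100, 100, dimnames = list(rownames(m), rownames(m)))
  d[1:50, 1:50] <- 0.1; d[51:100, 51:100] <- 0.1
  diag(d) <- 0
  hc <- average_linkage_cluster(d)
  cut <- dynamic_cut(hc, min_module_size = 30)
  expect_equal(sort(unique(cut$module)), c("M1", "M2"))
  expect_equal(sum(cut$module == "unassigned"), 0)

  # a 10-gene block cannot reach the 30-gene minimum
  d10 <- matrix(1, 40, 40, dimnames = list(paste0("g", 1:40),
                                           paste0("g", 1:40)))
  d10[1:10, 1:10] <- 0.1; diag(d10) <- 0
  cut <- dynamic_cut(average_linkage_cluster(d10), min_module_size = 30)
  expect_true(all(cut$module == "unassigned"))
})

test_that("eigengenes are unit-norm oriented first principal components", {
  md <- toy_metadata(replicates = 1)
  # identical profiles: eigengene proportional to the shared profile
  prof <- c(1, 3, 2, 5, 4, 6, 8, 7)
  m <- rbind(a = prof, b = prof * 2 + 1, c = prof * 0.5 - 2)
  colnames(m) <- md$sample_id
  assign <- tibble::tibble(feature_id = c("a", "b", "c"), module = "M1")
  me <- module_eigengenes(m, assign)
  expect_equal(me$variance_explained[["M1"]], 1)
  expect_equal(sum(me$eigengenes["M1", ]^2), 1)
  expect_gt(cor(me$eigengenes["M1", ], prof), 0.999)

  # x and -x: variance explained 1, deterministic orientation
  m2 <- rbind(a = prof, b = -prof)
  colnames(m2) <- md$sample_id
  me2 <- module_eigengenes(m2, tibble::tibble(feature_id = c("a", "b"),
                                              module = "M1"))
  expect_equal(me2$variance_explained[["M1"]], 1)
  expect_gt(cor(me2$eigengenes["M1", ], prof), 0.999)  # first-gene rule

  # 3-gene module against a direct eigendecomposition oracle
  set.seed(5)
  m3 <- matrix(rnorm(24), 3, dimnames = list(c("a", "b", "c"),
                                             md$sample_id))
  me3 <- module_eigengenes(m3, tibble::tibble(feature_id = c("a", "b", "c"),
                                              module = "M1"))
  std <- t(scale(t(m3)))
  ev <- eigen(crossprod(std))  # samples x samples
  v1 <- ev$vectors[, 1]
  if (sum(v1 * colMeans(std)) < 0) v1 <- -v1
  expect_equal(unname(me3$eigengenes["M1", ]), v1, tolerance = 1e-9)
  expect_equal(me3$variance_explained[["M1"]],
               ev$values[1] / sum(ev$values), tolerance = 1e-9)
})

test_that("module merging is closest-first, thresholded and idempotent", {
  md <- toy_metadata(replicates = 1)
  set.seed(10)
  base <- rnorm(8)
  m <- rbind(a1 = base + rnorm(8, sd = 0.01),
             a2 = base + rnorm(8, sd = 0.01),
             b1 = rnorm(8),
             b2 = rnorm(8))
  colnames(m) <- md$sample_id
  assign <- tibble::tibble(feature_id = rownames(m),
                           module = c("m1", "m1", "m2", "m3"))
  # identical eigengenes merge; unrelated ones do not
  ms <- merge_modules(m, tibble::tibble(
    feature_id = rownames(m), module = c("m1", "m2", "m3", "m3")))
  d12 <- 1 - cor(m["a1", ], m["a2", ])
  expect_lt(d12, 0.1)
  got <- ms$assignments$module
  expect_equal(got[1], got[2])        # near-identical profiles merged
  expect_false(got[1] == got[3])      # uncorrelated module kept apart

  # idempotence: rerunning changes nothing
  ms2 <- merge_modules(m, ms$assignments)
  expect_equal(ms$assignments, ms2$assignments)
  expect_equal(ms$eigengenes, ms2$eigengenes)
})

test_that("chained merges resolve closest-first and deterministically", {
  # modules A ~ B and B ~ C are close, A ~ C is not; the closest-first rule
  # fixes the merge order, and reruns give identical results
  md <- toy_metadata(replicates = 1:2)
  n_s <- nrow(md)
  set.seed(6)
  zA <- rnorm(n_s)
  zB <- zA + rnorm(n_s, sd = 0.15)
  zC <- zB + rnorm(n_s, sd = 0.15)
  mk <- function(z, tag) {
    out <- t(vapply(1:5, function(i) z + rnorm(n_s, sd = 0.05),
                    numeric(n_s)))
    rownames(out) <- paste0(tag, 1:5)
    out
  }
  m <- rbind(mk(zA, "a"), mk(zB, "b"), mk(zC, "c"))
  colnames(m) <- md$sample_id
  assign <- tibble::tibble(feature_id = rownames(m),
                           module = rep(c("A", "B", "C"), each = 5))
  ms1 <- merge_modules(m, assign, merge_dissimilarity = 0.1)
  ms2 <- merge_modules(m, assign, merge_dissimilarity = 0.1)
  expect_identical(ms1$assignments, ms2$assignments)
  # all three end up together through the A-B, then AB-C chain
  expect_equal(length(unique(ms1$assignments$module)), 1)
})

test_that("module-trait statistics follow the t-distribution formula", {
  eig <- rbind(M1 = c(1, 2, 3, 4) / sqrt(30),
               M2 = c(1, -1, 1, -1) / 2)
  colnames(eig) <- paste0("s", 1:4)
  traits <- tibble::tibble(sample_id = paste0("s", 1:4),
                           group = c(0, 0, 1, 1),
                           flat = c(1, 1, 1, 1))
  suppressMessages(mt <- module_trait_correlation(eig, traits))
  r_m1 <- mt$r[mt$module == "M1" & mt$trait == "group"]
  expect_equal(r_m1, 2 / sqrt(5), tolerance = 1e-9)  # 0.894...
  tstat <- r_m1 * sqrt(2 / (1 - r_m1^2))
  expect_equal(mt$p[mt$module == "M1" & mt$trait == "group"],
               2 * pt(-abs(tstat), df = 2), tolerance = 1e-12)
  # orthogonal eigengene-trait pair has r = 0
  expect_equal(mt$r[mt$module == "M2" & mt$trait == "group"], 0)
  # constant trait is reported as NA, excluded from the adjustment family
  expect_true(all(is.na(mt$fdr[mt$trait == "flat"])))
  ok <- !is.na(mt$p)
  expect_equal(mt$fdr[ok], p.adjust(mt$p[ok], "BH"))

  # eigengene equal to (scaled) trait gives r = 1
  traits2 <- tibble::tibble(sample_id = paste0("s", 1:4),
                            ramp = c(1, 2, 3, 4))
  mt2 <- module_trait_correlation(eig["M1", , drop = FALSE], traits2)
  expect_equal(mt2$r, 1, tolerance = 1e-12)
})

test_that("the full chain recovers planted modules on synthetic data", {
  cfg <- simulation_config(seed = 11, species = "Ath", n_genes = 440,
                           ortho_fraction = 1, module_sizes = rep(60, 4),
                           module_cor = 0.8,
                           module_traits = c("treatment", "timepoint",
                                             "none", "none"),
                           n_responders = 0)
  sim <- simulate_expression(cfg)
  g <- aggregate_transcripts_to_genes(sim$species_data$Ath$tpm,
                                      sim$species_data$Ath$tx2gene)
  ms <- detect_modules(log2_transform(g))
  truth <- dplyr::filter(sim$truth$modules, species == "Ath")
  joined <- dplyr::left_join(truth, ms$assignments,
                             by = c(gene_id = "feature_id"))
  ari <- adjusted_rand_index(joined$module.x, joined$module.y)
  expect_gte(ari, 0.9)
  # cross-check the ARI implementation against an independent one
  skip_if_not_installed("mclust")
  expect_equal(ari, mclust::adjustedRandIndex(joined$module.x,
                                              joined$module.y))
})
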