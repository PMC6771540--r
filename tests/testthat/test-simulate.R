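small_cfg <- function(seed = 51, ...) {
  simulation_config(seed = seed, n_genes = 80, module_sizes = c(15, 15),
                    module_traits = c("treatment", "none"),
                    n_responders = 15, ...)
}

test_that("the generators are fully deterministic under a seed", {
  a <- simulate_expression(small_cfg())
  b <- simulate_expression(small_cfg())
  expect_identical(a, b)
  expect_false(identical(
    expr_values(a$species_data$Ath$tpm),
    expr_values(simulate_expression(small_cfg(seed = 52))$species_data$Ath$tpm)))

  oa <- simulate_orthology(a$truth$ortho, seed = 3)
  ob <- simulate_orthology(a$truth$ortho, seed = 3)
  expect_identical(oa, ob)

  ga <- simulate_growth(species = "Ath", seed = 4)
  gb <- simulate_growth(species = "Ath", seed = 4)
  expect_identical(ga, gb)
})

test_that("the study design matches the declared layout", {
  sim <- simulate_expression(small_cfg())
  expect_named(sim$species_data, c("Ath", "Aly", "Esa"))
  si <- sample_info(sim$species_data$Aly$tpm)
  expect_equal(nrow(si), 2 * 4 * 3)  # conditions x timepoints x replicates
  expect_equal(levels(si$timepoint), c("T0", "T5", "T11", "T14"))
  expect_setequal(as.character(unique(si$condition)), c("WW", "WD"))
  expect_true(all(expr_values(sim$species_data$Ath$tpm) >= 0))
})

test_that("perfect within-module correlation is achieved at rho = 1", {
  # high baselines keep every value clear of the zero-TPM floor, where
  # clipping would otherwise distort the planted correlation
  cfg <- simulation_config(seed = 51, n_genes = 80,
                           module_sizes = c(15, 15),
                           module_traits = c("treatment", "none"),
                           module_cor = 1, noise_sd = 0, n_responders = 0,
                           baseline_meanlog = 5, baseline_sdlog = 0.3,
                           module_signal_sd = 1)
  sim <- simulate_expression(cfg)
  g <- aggregate_transcripts_to_genes(sim$species_data$Ath$tpm,
                                      sim$species_data$Ath$tx2gene)
  truth <- dplyr::filter(sim$truth$modules, species == "Ath",
                         module == "module1")
  m <- expr_values(log2_transform(g))[truth$gene_id, ]
  cors <- cor(t(m))
  expect_equal(min(cors), 1, tolerance = 1e-9)
})

test_that("planted fold changes are measured exactly without noise", {
  cfg <- simulation_config(seed = 53, n_genes = 100,
                           module_sizes = integer(),
                           module_traits = character(),
                           n_responders = 30, noise_sd = 0)
  sim <- simulate_expression(cfg)
  for (sp in c("Ath", "Esa")) {
    g <- aggregate_transcripts_to_genes(sim$species_data[[sp]]$tpm,
                                        sim$species_data[[sp]]$tx2gene)
    fc <- log2_fold_change(g)
    fc$timepoint <- as.character(fc$timepoint)
    truth <- dplyr::filter(sim$truth$fc_profiles, species == sp)
    joined <- dplyr::inner_join(
      fc, truth, by = c("species", "gene_id", "timepoint"),
      suffix = c("", ".planted"))
    expect_equal(nrow(joined), nrow(truth))
    expect_lt(max(abs(joined$log2fc - joined$log2fc.planted)), 1e-9)
    # non-responders stay flat
    flat <- dplyr::anti_join(fc, truth,
                             by = c("species", "gene_id", "timepoint"))
    expect_lt(max(abs(flat$log2fc)), 1e-9)
  }
})

test_that("emitted files round-trip through the pipeline readers cleanly", {
  sim <- simulate_expression(small_cfg())
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  expect_no_warning({
    back <- read_tpm_table(paths$Ath[["expression"]],
                           paths$Ath[["metadata"]])
  })
  expect_equal(expr_values(back), expr_values(sim$species_data$Ath$tpm))

  orth <- simulate_orthology(sim$truth$ortho, seed = 9)
  hit_path <- file.path(dir, "ath_vs_aly.tsv")
  write_blast_tab(orth$hits$Ath_vs_Aly, hit_path)
  expect_no_warning(hits <- read_blast_tab(hit_path, max_evalue = 1))
  expect_equal(hits$bitscore, orth$hits$Ath_vs_Aly$bitscore)
  expect_equal(hits$evalue, orth$hits$Ath_vs_Aly$evalue)
})

test_that("orthology generator honours decoy and missing rates", {
  sim <- simulate_expression(small_cfg())
  # missing rate 1 leaves no complete triples
  orth <- simulate_orthology(sim$truth$ortho, missing_rate = 1, seed = 5)
  expect_equal(nrow(orth$triples), 0)
  expect_equal(nrow(orth$hits$Ath_vs_Aly), 0)
  # decoys never outscore the true hit for the same query
  orth2 <- simulate_orthology(sim$truth$ortho, decoy_rate = 0.5, seed = 6)
  fwd <- orth2$hits$Ath_vs_Aly
  truth_map <- setNames(sim$truth$ortho$Aly, sim$truth$ortho$Ath)
  best <- fwd %>%
    dplyr::group_by(qseqid) %>%
    dplyr::slice_max(bitscore, n = 1) %>%
    dplyr::ungroup()
  expect_true(all(best$sseqid == truth_map[best$qseqid]))
})

test_that("growth curves respect their planted structure", {
  # no noise and no divergence: the two arms coincide exactly
  p0 <- list(noise_sd = 0, plant_sd = 0, divergence_day = c(Ath = Inf),
             n_plants_per_replicate = 3, n_replicates = 1)
  g0 <- simulate_growth("Ath", p0, seed = 7)
  ww <- dplyr::filter(g0$series, treatment == "WW")
  wd <- dplyr::filter(g0$series, treatment == "WD")
  expect_equal(ww$area, wd$area)
  expect_equal(ww$perimeter, wd$perimeter)

  g <- simulate_growth(params = list(n_plants_per_replicate = 5,
                                     n_replicates = 2), seed = 8)
  st <- stockiness(g$series$area, g$series$perimeter)
  cp <- compactness(g$series$area, g$series$hull_area)
  expect_true(all(st > 0 & st <= 1))
  expect_true(all(cp > 0 & cp <= 1))
  expect_true(all(g$series$survived[g$series$treatment == "WW"]))
})
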