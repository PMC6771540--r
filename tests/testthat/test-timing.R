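test_that("fold changes use pseudocounted replicate means", {
  md <- toy_metadata(timepoints = c("T0", "T5"), replicates = 1:2)
  # rows: equal means; WD mean 3 vs WW mean 1; all-zero gene
  vals <- rbind(c(5, 5, 2, 8, 5, 5, 2, 8),
                c(1, 1, 1, 1, 1, 1, 3, 3),
                c(0, 0, 0, 0, 0, 0, 0, 0))
  x <- toy_expr(vals, md)
  fc <- log2_fold_change(x)
  get <- function(g, tp) fc$log2fc[fc$gene_id == g & fc$timepoint == tp]
  expect_equal(get("g001", "T5"), 0)          # symmetric means
  expect_equal(get("g002", "T5"), 1)          # log2((3+1)/(1+1))
  expect_equal(get("g003", "T5"), 0)          # 0/0 guarded by pseudocount

  # a timepoint missing one condition is skipped with a warning
  ww_only <- x[, c(1, which(sample_info(x)$condition == "WW" |
                              sample_info(x)$timepoint == "T5") + 1)]
  expect_warning(fc2 <- log2_fold_change(ww_only), "lacks WD")
  expect_false("T0" %in% as.character(fc2$timepoint))
})

test_that("regulation calls use inclusive thresholds", {
  fc <- tibble::tibble(species = "Ath", gene_id = paste0("g", 1:4),
                       timepoint = "T11",
                       log2fc = c(1.0, -1.0, 0.5, 2.3))
  calls <- call_regulated(fc)
  expect_equal(as.character(calls$status), c("up", "down", "ns", "up"))
  expect_error(call_regulated(fc, up = -1, down = 1), "exceed")
  counts <- de_counts(calls)
  expect_equal(counts$n_genes[counts$status == "up"], 2L)
})

test_that("drought-specific genes are off in WW and before onset", {
  md <- toy_metadata(timepoints = c("T0", "T11"), replicates = 1)
  # columns: WW_T0 WW_T11 WD_T0 WD_T11
  vals <- rbind(c(0, 0, 0, 2.0),   # induced only under WD: included
                c(1.5, 0, 0, 2.0), # already on at T0: excluded
                c(0, 0, 0, 0.5))   # never reaches threshold: excluded
  x <- toy_expr(vals, md, scale = "log2tpm")
  hits <- drought_specific_genes(x)
  expect_equal(hits$gene_id, "g001")
})

test_that("peak timing and segments follow the fold-change course", {
  fc1 <- tibble::tibble(emo_id = "e1", species = "Ath",
                        timepoint = factor(c("T5", "T11", "T14"),
                                           levels = c("T5", "T11", "T14"),
                                           ordered = TRUE),
                        log2fc = c(0.2, 1.5, 1.2))
  prof <- classify_peak_timing(fc1)
  expect_true(prof$induced)
  expect_equal(as.character(prof$first_peak), "T11")
  expect_equal(as.character(prof$highest_peak), "T11")
  expect_equal(prof$segment, "Ath-specific")

  fc2 <- fc1; fc2$log2fc <- c(1.1, 0.8, 2.0)
  prof <- classify_peak_timing(fc2)
  expect_equal(as.character(prof$first_peak), "T5")
  expect_equal(as.character(prof$highest_peak), "T14")

  # three species, two synchronous and one silent
  fc3 <- tidyr::expand_grid(emo_id = "e1",
                            species = c("Ath", "Aly", "Esa"),
                            timepoint = c("T5", "T11", "T14"))
  fc3$log2fc <- ifelse(fc3$species == "Esa", 0,
                       ifelse(fc3$timepoint == "T11", 2, 0))
  prof <- classify_peak_timing(fc3, species_order = c("Ath", "Aly", "Esa"))
  expect_equal(unique(prof$segment), "Ath+Aly-synchronous")

  # all species induced, different first peaks
  fc4 <- fc3
  fc4$log2fc <- dplyr::case_when(
    fc4$species == "Ath" & fc4$timepoint == "T5" ~ 2,
    fc4$species == "Aly" & fc4$timepoint == "T11" ~ 2,
    fc4$species == "Esa" & fc4$timepoint == "T14" ~ 2,
    TRUE ~ 0)
  prof <- classify_peak_timing(fc4, species_order = c("Ath", "Aly", "Esa"))
  expect_equal(unique(prof$segment), "common-shifted")
})

test_that("sub-threshold timepoints do not change the classification", {
  base <- tibble::tibble(emo_id = "e1", species = "Ath",
                         timepoint = factor(c("T11", "T14"),
                                            levels = c("T5", "T11", "T14"),
                                            ordered = TRUE),
                         log2fc = c(1.4, 2.2))
  extended <- dplyr::bind_rows(
    tibble::tibble(emo_id = "e1", species = "Ath",
                   timepoint = factor("T5", levels = c("T5", "T11", "T14"),
                                      ordered = TRUE),
                   log2fc = 0.7), base)
  a <- classify_peak_timing(base)
  b <- classify_peak_timing(extended)
  expect_equal(a$first_peak, b$first_peak)
  expect_equal(a$highest_peak, b$highest_peak)
  expect_equal(a$segment, b$segment)
})

test_that("overlap regions are exclusive and sum to the union", {
  sets <- list(A = c("a", "b", "c"), B = c("b", "c"), C = "c")
  v <- venn_overlaps(sets)
  expect_equal(v$count[v$region == "A&B&C"], 1L)
  expect_equal(v$count[v$region == "A"], 1L)
  expect_equal(sum(v$count), length(unique(unlist(sets))))

  disjoint <- list(A = "a", B = "b", C = "c")
  expect_equal(venn_overlaps(disjoint)$count[7], 0L)

  same <- list(A = letters[1:5], B = letters[1:5], C = letters[1:5])
  v <- venn_overlaps(same)
  expect_equal(v$count[v$region == "A&B&C"], 5L)

  # property: counts always partition the union
  for (seed in 1:5) {
    set.seed(seed)
    sets <- lapply(setNames(1:3, c("x", "y", "z")), function(i) {
      sample(letters, sample(3:15, 1))
    })
    v <- venn_overlaps(sets)
    expect_equal(sum(v$count), length(unique(unlist(sets))))
  }
})

test_that("planted timing classes are recovered from noisy fold changes", {
  tp <- simulate_timing_profiles(n_emo = 400, noise_sd = 0.1, seed = 31)
  cls <- classify_peak_timing(tp$fc, species_order = c("Ath", "Aly", "Esa"))
  seg <- dplyr::distinct(cls[c("emo_id", "segment")])
  joined <- dplyr::inner_join(seg, tp$truth, by = "emo_id")
  acc <- mean(joined$segment.x == joined$segment.y)
  expect_gte(acc, 0.99)
})
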