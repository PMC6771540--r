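#' Water-deficit versus well-watered log2 fold change
#'
#' For each gene, species and timepoint, computes
#' `log2((mean TPM_WD + c) / (mean TPM_WW + c))` over the biological
#' replicates, with pseudocount `c` guarding against division by zero and
#' damping ratios of barely expressed genes. Timepoints lacking one of the
#' two conditions are skipped with a warning.
#'
#' @param x An [expr_tbl] on the TPM scale containing WW and WD samples.
#' @param pseudocount Offset added to the replicate means (default 1,
#'   matching the expression-filter scale).
#' @return A tibble with columns `species`, `gene_id`, `timepoint`
#'   (ordered factor), `log2fc`.
#' @export
log2_fold_change <- function(x, pseudocount = 1) {
  stopifnot(inherits(x, "expr_tbl"))
  if (expr_scale(x) != "tpm") {
    abort("Fold changes are computed from TPM-scale values.")
  }
  check_number(pseudocount, "pseudocount", lower = 0)
  si <- sample_info(x)
  m <- expr_values(x)
  tp_levels <- levels(si$timepoint)
  out <- list()
  for (sp in unique(si$species)) {
    for (tp in tp_levels) {
      in_cell <- si$species == sp & si$timepoint == tp
      wd <- which(in_cell & si$condition == "WD")
      ww <- which(in_cell & si$condition == "WW")
      if (!any(in_cell)) next
      if (length(wd) == 0 || length(ww) == 0) {
        warn(sprintf("Timepoint %s (%s) lacks %s samples; skipped.", tp, sp,
                     if (length(wd) == 0) "WD" else "WW"))
        next
      }
      fc <- log2((rowMeans(m[, wd, drop = FALSE]) + pseudocount) /
                   (rowMeans(m[, ww, drop = FALSE]) + pseudocount))
      out[[length(out) + 1]] <- tibble::tibble(
        species = sp, gene_id = rownames(m), timepoint = tp,
        log2fc = unname(fc))
    }
  }
  res <- bind_rows(out)
  res$timepoint <- factor(res$timepoint, levels = tp_levels, ordered = TRUE)
  res
}

#' Call regulated genes from fold changes
#'
#' Thresholds are inclusive: `log2fc >= up` is called "up" and
#' `log2fc <= down` is called "down"; everything between is "ns".
#'
#' @param fc A fold-change tibble from [log2_fold_change()].
#' @param up,down Inclusive log2 fold-change thresholds (defaults +1 / -1).
#' @return `fc` with an added `status` factor (`up`/`down`/`ns`).
#' @export
call_regulated <- function(fc, up = 1, down = -1) {
  check_number(up, "up")
  check_number(down, "down")
  if (up <= down) abort("`up` must exceed `down`.")
  mutate(fc, status = factor(
    dplyr::case_when(.data$log2fc >= up ~ "up",
                     .data$log2fc <= down ~ "down",
                     TRUE ~ "ns"),
    levels = c("up", "down", "ns")))
}

#' Count regulated genes per species, timepoint and direction
#'
#' @param calls Output of [call_regulated()].
#' @return A count tibble (the per-species bar heights of a differential
#'   expression summary figure).
#' @export
de_counts <- function(calls) {
  calls %>%
    filter(.data$status != "ns") %>%
    count(.data$species, .data$timepoint, .data$status, .drop = FALSE,
          name = "n_genes") %>%
    filter(.data$status != "ns")
}

#' Genes expressed only under water deficit
#'
#' Identifies genes switched on by drought: expressed (log2TPM at or above
#' the threshold) in at least one water-deficit sample after stress onset,
#' but below threshold in every well-watered sample and in every sample taken
#' at the first timepoint (before the treatment could act). Genes already
#' expressed before stress onset are thereby excluded.
#'
#' @param x An [expr_tbl] on the log2tpm scale with WW and WD samples
#'   including the onset timepoint.
#' @param threshold Inclusive expression threshold (default 1).
#' @return A tibble with columns `species` and `gene_id`.
#' @export
drought_specific_genes <- function(x, threshold = 1) {
  stopifnot(inherits(x, "expr_tbl"))
  if (expr_scale(x) != "log2tpm") {
    abort("`drought_specific_genes()` expects a log2tpm-scale table.")
  }
  check_number(threshold, "threshold")
  si <- sample_info(x)
  m <- expr_values(x)
  t0 <- levels(si$timepoint)[1]
  out <- list()
  for (sp in unique(si$species)) {
    sp_idx <- si$species == sp
    wd_post <- which(sp_idx & si$condition == "WD" & si$timepoint != t0)
    baseline <- which(sp_idx & (si$condition == "WW" | si$timepoint == t0))
    if (length(wd_post) == 0 || length(baseline) == 0) next
    on_in_wd <- apply(m[, wd_post, drop = FALSE], 1, max) >= threshold
    off_at_base <- apply(m[, baseline, drop = FALSE], 1, max) < threshold
    hits <- rownames(m)[on_in_wd & off_at_base]
    out[[sp]] <- tibble::tibble(species = sp, gene_id = hits)
  }
  bind_rows(out)
}

segment_code <- function(species_order, induced_species, first_peaks) {
  k <- length(induced_species)
  if (k == 0) return("none")
  sps <- species_order[species_order %in% induced_species]
  if (k == 1) return(paste0(sps, "-specific"))
  timing <- if (length(unique(first_peaks)) == 1) "synchronous" else "shifted"
  prefix <- if (k == length(species_order)) "common" else paste(sps, collapse = "+")
  paste(prefix, timing, sep = "-")
}

#' Classify per-species response timing of orthologs
#'
#' For each ortholog (EMO) and species, a gene is "induced" when its log2
#' fold change reaches the `up` threshold at any post-onset timepoint; its
#' first peak is the earliest such timepoint and its highest peak the
#' timepoint of the maximal fold change among induced timepoints (earliest
#' wins ties). Each EMO then receives a cross-species segment label built
#' from which species are induced and whether their first peaks agree:
#' `"common-synchronous"`, `"common-shifted"`, pair codes such as
#' `"Ath+Aly-shifted"`, single-species codes such as `"Esa-specific"`, or
#' `"none"`.
#'
#' @param fc A tibble with columns `emo_id`, `species`, `timepoint`,
#'   `log2fc`, giving fold changes at the post-onset timepoints for every
#'   species of each EMO.
#' @param up Inclusive induction threshold on log2 fold change (default 1).
#' @param species_order Order in which species appear in segment codes;
#'   defaults to order of appearance in `fc`.
#' @return A tibble with one row per EMO x species (`induced`, `first_peak`,
#'   `highest_peak`) plus the shared `segment` label.
#' @export
classify_peak_timing <- function(fc, up = 1, species_order = NULL) {
  check_number(up, "up")
  stopifnot(all(c("emo_id", "species", "timepoint", "log2fc") %in% names(fc)))
  tp_levels <- if (is.factor(fc$timepoint)) {
    levels(fc$timepoint)
  } else {
    unique(as.character(fc$timepoint))
  }
  species_order <- species_order %||% unique(as.character(fc$species))
  fc <- mutate(fc,
               timepoint = factor(as.character(.data$timepoint),
                                  levels = tp_levels, ordered = TRUE))
  per_sp <- fc %>%
    group_by(.data$emo_id, .data$species) %>%
    arrange(.data$timepoint, .by_group = TRUE) %>%
    summarise(induced = any(.data$log2fc >= up),
              first_peak = if (any(.data$log2fc >= up)) {
                as.character(.data$timepoint[which(.data$log2fc >= up)[1]])
              } else NA_character_,
              highest_peak = if (any(.data$log2fc >= up)) {
                cand <- which(.data$log2fc >= up)
                as.character(.data$timepoint[cand[which.max(.data$log2fc[cand])]])
              } else NA_character_,
              .groups = "drop")
  segments <- per_sp %>%
    group_by(.data$emo_id) %>%
    summarise(segment = segment_code(species_order,
                                     .data$species[.data$induced],
                                     .data$first_peak[.data$induced]),
              .groups = "drop")
  out <- left_join(per_sp, segments, by = "emo_id")
  out$first_peak <- factor(out$first_peak, levels = tp_levels, ordered = TRUE)
  out$highest_peak <- factor(out$highest_peak, levels = tp_levels,
                             ordered = TRUE)
  out
}

#' Exclusive region counts of overlapping gene sets
#'
#' Counts every exclusive region of the Venn diagram of the supplied sets
#' (all `2^k - 1` regions for `k` sets). Region counts always sum to the size
#' of the union.
#'
#' @param sets A named list of character vectors over a shared id space.
#' @return A tibble with columns `region` (set names joined by `&`) and
#'   `count`, including zero-count regions.
#' @export
venn_overlaps <- function(sets) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("`sets` must be a fully named list.")
  }
  k <- length(sets)
  ids <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
  membership <- matrix(membership, nrow = length(ids))
  patterns <- apply(membership, 1, function(row) {
    paste(names(sets)[row], collapse = "&")
  })
  combos <- unlist(lapply(seq_len(k), function(size) {
    apply(utils::combn(names(sets), size), 2, paste, collapse = "&")
  }))
  counts <- table(factor(patterns, levels = combos))
  tibble::tibble(region = combos, count = as.integer(counts[combos]))
}
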