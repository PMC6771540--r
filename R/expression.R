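#' Expression tables with attached sample annotations
#'
#' `expr_tbl()` builds the package's central object: a tibble with a
#' `feature_id` column followed by one numeric column per sample, carrying the
#' per-sample annotations (species, watering condition, timepoint, replicate)
#' and the abundance scale (`"tpm"` or `"log2tpm"`) as attributes. All
#' expression operations take and return this class so analyses chain with the
#' pipe.
#'
#' @param values A data frame whose first column is `feature_id` (unique
#'   transcript or gene identifiers) and whose remaining columns are
#'   nonnegative TPM (or log2-scale) values, one column per sample.
#' @param sample_info A data frame of sample annotations with columns
#'   `sample_id`, `species`, `condition` (`"WW"`/`"WD"`), `timepoint` and
#'   `replicate`; every expression column must appear in `sample_id`.
#' @param scale Either `"tpm"` or `"log2tpm"`.
#' @param timepoint_levels Ordering of the timepoints; defaults to the
#'   T0 < T5 < T11 < T14 drought course when those labels are used, otherwise
#'   order of appearance.
#' @return An `expr_tbl`, a tibble subclass.
#' @export
expr_tbl <- function(values, sample_info, scale = c("tpm", "log2tpm"),
                     timepoint_levels = NULL) {
  scale <- match.arg(scale)
  values <- tibble::as_tibble(values)
  if (names(values)[1] != "feature_id") {
    names(values)[1] <- "feature_id"
  }
  values$feature_id <- as.character(values$feature_id)
  dup <- values$feature_id[duplicated(values$feature_id)]
  if (length(dup) > 0) {
    abort(sprintf("Duplicate feature ids are not allowed: %s",
                  paste(unique(dup), collapse = ", ")))
  }
  sample_cols <- names(values)[-1]
  sample_info <- normalise_sample_info(sample_info, timepoint_levels)
  missing <- setdiff(sample_cols, sample_info$sample_id)
  if (length(missing) > 0) {
    abort(sprintf("No sample metadata for column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  sample_info <- sample_info[match(sample_cols, sample_info$sample_id), ]
  for (col in sample_cols) {
    v <- values[[col]]
    if (!is.numeric(v)) {
      abort(sprintf("Column '%s' is not numeric.", col))
    }
    if (scale == "tpm" && any(v < 0, na.rm = TRUE)) {
      abort(sprintf("TPM values must be nonnegative; column '%s' has negatives.",
                    col))
    }
  }
  new_expr_tbl(values, sample_info, scale)
}

new_expr_tbl <- function(values, sample_info, scale) {
  tibble::new_tibble(values, sample_info = sample_info, scale = scale,
                     class = "expr_tbl", nrow = nrow(values))
}

normalise_sample_info <- function(sample_info, timepoint_levels = NULL) {
  sample_info <- tibble::as_tibble(sample_info)
  required <- c("sample_id", "species", "condition", "timepoint", "replicate")
  missing <- setdiff(required, names(sample_info))
  if (length(missing) > 0) {
    abort(sprintf("Sample metadata is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(sample_info$sample_id)) {
    abort("`sample_id` must be unique within the metadata.")
  }
  bad <- setdiff(unique(as.character(sample_info$condition)), c("WW", "WD"))
  if (length(bad) > 0) {
    abort(sprintf("`condition` must be WW or WD; found: %s",
                  paste(bad, collapse = ", ")))
  }
  tp <- as.character(sample_info$timepoint)
  if (is.null(timepoint_levels)) {
    timepoint_levels <- if (all(tp %in% drought_timepoints)) {
      intersect(drought_timepoints, tp)
    } else {
      unique(tp)
    }
  }
  sample_info$sample_id <- as.character(sample_info$sample_id)
  sample_info$species <- as.character(sample_info$species)
  sample_info$condition <- factor(as.character(sample_info$condition),
                                  levels = c("WW", "WD"))
  sample_info$timepoint <- factor(tp, levels = timepoint_levels, ordered = TRUE)
  sample_info$replicate <- as.integer(sample_info$replicate)
  if (any(is.na(sample_info$timepoint))) {
    abort("Some timepoints are outside the supplied `timepoint_levels`.")
  }
  if (any(sample_info$replicate < 1, na.rm = TRUE)) {
    abort("`replicate` must be a positive integer.")
  }
  sample_info
}

#' Accessors for expression tables
#'
#' @param x An [expr_tbl].
#' @return `sample_info()` returns the annotation tibble (one row per
#'   expression column, in column order); `expr_scale()` the scale string;
#'   `expr_values()` a numeric features-by-samples matrix with feature ids as
#'   row names.
#' @export
sample_info <- function(x) {
  stopifnot(inherits(x, "expr_tbl"))
  attr(x, "sample_info")
}

#' @rdname sample_info
#' @export
expr_scale <- function(x) {
  stopifnot(inherits(x, "expr_tbl"))
  attr(x, "scale")
}

#' @rdname sample_info
#' @export
expr_values <- function(x) {
  stopifnot(inherits(x, "expr_tbl"))
  m <- as.matrix(as.data.frame(x)[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x$feature_id
  m
}

#' @export
print.expr_tbl <- function(x, ...) {
  si <- sample_info(x)
  cat(sprintf("# expr_tbl: %d features x %d samples [%s scale]\n",
              nrow(x), nrow(si), expr_scale(x)))
  cat(sprintf("# species: %s | conditions: %s | timepoints: %s\n",
              paste(unique(si$species), collapse = ", "),
              paste(levels(droplevels(si$condition)), collapse = ", "),
              paste(levels(si$timepoint), collapse = " < ")))
  NextMethod()
}

#' @export
tidy.expr_tbl <- function(x, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(x), -"feature_id",
                              names_to = "sample_id", values_to = "value")
  left_join(long, sample_info(x), by = "sample_id")
}

#' @export
`[.expr_tbl` <- function(x, ...) {
  si <- attr(x, "sample_info")
  sc <- attr(x, "scale")
  out <- NextMethod()
  if (!is.data.frame(out) || !"feature_id" %in% names(out)) {
    return(out)
  }
  kept <- intersect(names(out)[-1], si$sample_id)
  new_expr_tbl(tibble::as_tibble(out),
               si[match(kept, si$sample_id), , drop = FALSE], sc)
}

# rebuild an expr_tbl from a values matrix, keeping annotations
expr_from_matrix <- function(m, sample_info, scale) {
  values <- tibble::as_tibble(m, .name_repair = "minimal")
  values <- tibble::add_column(values, feature_id = rownames(m), .before = 1)
  new_expr_tbl(values, sample_info, scale)
}

#' Read a TPM expression table with sample metadata
#'
#' Reads a tab-separated expression table (header row of sample ids, first
#' column of feature ids) and attaches per-sample annotations. Row and column
#' order are preserved from the file.
#'
#' @param path Path to the TSV expression table.
#' @param metadata A sample-annotation data frame (see [expr_tbl]), or a path
#'   to a metadata TSV readable by [read_sample_metadata()].
#' @inheritParams expr_tbl
#' @return An [expr_tbl] on the TPM scale.
#' @export
read_tpm_table <- function(path, metadata, timepoint_levels = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(raw) < 2) {
    abort("Expression table needs a feature column plus at least one sample.")
  }
  names(raw)[1] <- "feature_id"
  for (j in seq(2, ncol(raw))) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v) & !is.na(raw[[j]]))
    if (length(bad) > 0) {
      abort(sprintf("Non-numeric value '%s' at row %d, column '%s' of %s",
                    raw[[j]][bad[1]], bad[1], names(raw)[j], path))
    }
    raw[[j]] <- v
  }
  if (is.character(metadata) && length(metadata) == 1) {
    metadata <- read_sample_metadata(metadata, timepoint_levels)
  }
  expr_tbl(raw, metadata, scale = "tpm", timepoint_levels = timepoint_levels)
}

#' @rdname read_tpm_table
#' @export
read_sample_metadata <- function(path, timepoint_levels = NULL) {
  md <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  normalise_sample_info(md, timepoint_levels)
}

#' Write an expression table (and metadata) as TSV
#'
#' Inverse of [read_tpm_table()]; numbers are written in full precision so a
#' write-then-read round trip reproduces values exactly.
#'
#' @param x An [expr_tbl].
#' @param path Output TSV path for the expression values.
#' @param metadata_path Optional output path for the sample annotations.
#' @return `x`, invisibly.
#' @export
write_tpm_table <- function(x, path, metadata_path = NULL) {
  stopifnot(inherits(x, "expr_tbl"))
  out <- tibble::as_tibble(x)
  out[-1] <- lapply(out[-1], function(v) sprintf("%.17g", v))
  readr::write_tsv(out, path, progress = FALSE)
  if (!is.null(metadata_path)) {
    si <- sample_info(x)
    si$timepoint <- as.character(si$timepoint)
    si$condition <- as.character(si$condition)
    readr::write_tsv(si, metadata_path, progress = FALSE)
  }
  invisible(x)
}

#' Sum transcript TPM into gene TPM
#'
#' Gene abundance is the sum of the TPM of its transcripts, computed per
#' sample. Because TPM is a linear within-sample unit this conserves each
#' sample's total when no transcript is dropped.
#'
#' @param x A transcript-level [expr_tbl] on the TPM scale.
#' @param map A data frame with columns `transcript_id` and `gene_id`; each
#'   transcript must map to exactly one gene.
#' @param unmapped What to do with transcripts absent from `map`: `"error"`
#'   (default) or `"drop"`.
#' @return A gene-level [expr_tbl] (genes in order of first appearance of
#'   their transcripts).
#' @export
aggregate_transcripts_to_genes <- function(x, map,
                                           unmapped = c("error", "drop")) {
  stopifnot(inherits(x, "expr_tbl"))
  unmapped <- match.arg(unmapped)
  if (expr_scale(x) != "tpm") {
    abort("Transcript aggregation operates on the TPM scale.")
  }
  map <- tibble::as_tibble(map)
  stopifnot(all(c("transcript_id", "gene_id") %in% names(map)))
  if (anyDuplicated(map$transcript_id)) {
    abort("Each transcript must map to exactly one gene.")
  }
  gene <- map$gene_id[match(x$feature_id, map$transcript_id)]
  if (anyNA(gene)) {
    lost <- x$feature_id[is.na(gene)]
    if (unmapped == "error") {
      abort(sprintf("%d transcript(s) missing from the map, e.g. %s",
                    length(lost), paste(head(lost, 3), collapse = ", ")))
    }
    keep <- !is.na(gene)
    x <- x[keep, ]
    gene <- gene[keep]
  }
  m <- expr_values(x)
  agg <- rowsum(m, group = gene, reorder = FALSE)
  expr_from_matrix(agg, sample_info(x), "tpm")
}

#' Log2 transform of TPM values
#'
#' Computes `log2(TPM + pseudocount)`; the default pseudocount of 1 makes the
#' conventional expression cutoff log2TPM >= 1 equivalent to TPM >= 1.
#'
#' @param x An [expr_tbl] on the TPM scale.
#' @param pseudocount Nonnegative offset added before taking logs.
#' @return An [expr_tbl] with scale `"log2tpm"`.
#' @export
log2_transform <- function(x, pseudocount = 1) {
  stopifnot(inherits(x, "expr_tbl"))
  if (expr_scale(x) != "tpm") {
    abort("`log2_transform()` expects a TPM-scale table.")
  }
  check_number(pseudocount, "pseudocount", lower = 0)
  m <- log2(expr_values(x) + pseudocount)
  expr_from_matrix(m, sample_info(x), "log2tpm")
}

#' Filter genes by minimum expression
#'
#' Retains features whose maximum log2-scale value across samples reaches the
#' threshold in at least one sample (the comparison is inclusive, so a feature
#' hitting exactly the threshold is kept). Retained/dropped counts are
#' reported and stored in the `"filter_counts"` attribute.
#'
#' @param x An [expr_tbl] on the log2tpm scale.
#' @param threshold Minimum log2TPM required in at least one sample
#'   (default 1).
#' @param quiet Suppress the count message.
#' @return The filtered [expr_tbl].
#' @export
expression_filter <- function(x, threshold = 1, quiet = FALSE) {
  stopifnot(inherits(x, "expr_tbl"))
  if (expr_scale(x) != "log2tpm") {
    abort("`expression_filter()` expects a log2tpm-scale table (see `log2_transform()`).")
  }
  check_number(threshold, "threshold")
  m <- expr_values(x)
  keep <- apply(m, 1, max) >= threshold
  out <- x[keep, ]
  counts <- c(retained = sum(keep), dropped = sum(!keep))
  attr(out, "filter_counts") <- counts
  if (!quiet) {
    inform(sprintf("expression_filter: retained %d features, dropped %d (threshold %g)",
                   counts[["retained"]], counts[["dropped"]], threshold))
  }
  out
}

#' Average samples by metadata groups
#'
#' Collapses replicate samples by averaging over all samples sharing the
#' chosen metadata keys (e.g. `c("species", "condition", "timepoint")` for
#' replicate means feeding fold changes).
#'
#' @param x An [expr_tbl].
#' @param keys Character vector of sample-annotation columns to group by.
#' @return An [expr_tbl] with one column per distinct key combination; the
#'   attached annotations keep the key columns (non-key columns are collapsed
#'   to their first value and `replicate` is set to 1).
#' @export
mean_by_group <- function(x, keys = c("species", "condition", "timepoint")) {
  stopifnot(inherits(x, "expr_tbl"))
  si <- sample_info(x)
  if (length(keys) == 0) {
    abort("`keys` must name at least one metadata column.")
  }
  bad <- setdiff(keys, names(si))
  if (length(bad) > 0) {
    abort(sprintf("Unknown metadata key(s): %s", paste(bad, collapse = ", ")))
  }
  key_df <- si[keys]
  key_id <- do.call(paste, c(lapply(key_df, as.character), sep = "_"))
  groups <- unique(key_id)
  m <- expr_values(x)
  avg <- vapply(groups, function(g) rowMeans(m[, key_id == g, drop = FALSE]),
                numeric(nrow(m)))
  avg <- matrix(avg, nrow = nrow(m),
                dimnames = list(rownames(m), groups))
  new_si <- si[match(groups, key_id), ]
  new_si$sample_id <- groups
  if (!"replicate" %in% keys) new_si$replicate <- 1L
  expr_from_matrix(avg, new_si, expr_scale(x))
}

#' Subset an expression table to a set of features
#'
#' @param x An [expr_tbl].
#' @param features Character vector of feature ids to keep (order preserved
#'   from `features`; missing ids are an error).
#' @return The subset [expr_tbl].
#' @export
select_features <- function(x, features) {
  stopifnot(inherits(x, "expr_tbl"))
  idx <- match(features, x$feature_id)
  if (anyNA(idx)) {
    abort(sprintf("%d requested feature(s) not present, e.g. %s",
                  sum(is.na(idx)),
                  paste(head(features[is.na(idx)], 3), collapse = ", ")))
  }
  out <- x[idx, ]
  attributes(out)$sample_info <- sample_info(x)
  out
}
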