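#' Propagate gene annotations up a term DAG
#'
#' True-path closure: every gene annotated to a term is also annotated to all
#' of that term's ancestors, with set semantics (an ancestor reachable along
#' several paths is counted once). Idempotent. Cycles in the parent relation
#' are an error.
#'
#' @param annotation A tibble with columns `gene_id`, `term_id`.
#' @param parents A tibble with columns `term_id`, `parent_id` giving the
#'   child-to-parent edges of the term DAG, or `NULL` for a flat vocabulary.
#' @return The closed annotation tibble (`gene_id`, `term_id`), deduplicated.
#' @export
propagate_annotations <- function(annotation, parents = NULL) {
  annotation <- distinct(tibble::as_tibble(annotation)[c("gene_id", "term_id")])
  if (is.null(parents) || nrow(parents) == 0) {
    return(annotation)
  }
  parents <- tibble::as_tibble(parents)[c("term_id", "parent_id")]
  if (any(parents$term_id == parents$parent_id)) {
    abort("Self-loop in the term graph.")
  }
  parent_list <- split(parents$parent_id, parents$term_id)
  ancestors <- new.env(parent = emptyenv())
  state <- new.env(parent = emptyenv())  # "visiting" marks the DFS stack
  visit <- function(term) {
    st <- get0(term, envir = state, ifnotfound = "new")
    if (st == "visiting") {
      abort(sprintf("Cycle detected in the term graph at '%s'.", term))
    }
    if (st == "done") return(get0(term, envir = ancestors))
    assign(term, "visiting", envir = state)
    direct <- parent_list[[term]] %||% character()
    anc <- unique(c(direct, unlist(lapply(direct, visit), use.names = FALSE)))
    assign(term, anc, envir = ancestors)
    assign(term, "done", envir = state)
    anc
  }
  terms <- unique(c(annotation$term_id, parents$term_id))
  for (term in terms) visit(term)
  extra <- annotation %>%
    mutate(anc = lapply(.data$term_id, function(t) {
      get0(t, envir = ancestors, ifnotfound = character())
    })) %>%
    select("gene_id", term_id = "anc") %>%
    tidyr::unnest("term_id")
  distinct(bind_rows(annotation, extra))
}

#' One-sided term enrichment of a gene set
#'
#' For every annotated term, tests whether the study set contains more
#' member genes than expected from the universe, using the hypergeometric
#' upper tail `P(X >= k)` (equivalent to a one-sided Fisher exact test on the
#' 2x2 table). Terms with no annotated universe gene are skipped rather than
#' padded with p = 1, keeping the multiple-testing family honest; adjusted
#' values use the Benjamini-Hochberg step-up rule across the tested terms.
#'
#' @param study Character vector of study gene ids; must be a subset of
#'   `universe`.
#' @param universe Character vector of background gene ids (typically all
#'   expressed genes, or the EMO set for EMO-restricted analyses).
#' @param annotation A tibble with columns `gene_id`, `term_id`, ideally
#'   closed with [propagate_annotations()]. Universe genes without terms are
#'   allowed.
#' @return A tibble sorted by p-value with columns `term_id`, `k` (study
#'   hits), `n` (study size), `K` (universe hits), `N` (universe size), `p`,
#'   `fdr`.
#' @export
fisher_enrichment <- function(study, universe, annotation) {
  study <- unique(as.character(study))
  universe <- unique(as.character(universe))
  if (!all(study %in% universe)) {
    abort("`study` must be a subset of `universe`.")
  }
  annotation <- distinct(tibble::as_tibble(annotation)[c("gene_id", "term_id")])
  annotation <- filter(annotation, .data$gene_id %in% universe)
  if (nrow(annotation) == 0) {
    return(tibble::tibble(term_id = character(), k = integer(), n = integer(),
                          K = integer(), N = integer(), p = numeric(),
                          fdr = numeric()))
  }
  N <- length(universe)
  n <- length(study)
  per_term <- annotation %>%
    group_by(.data$term_id) %>%
    summarise(K = dplyr::n_distinct(.data$gene_id),
              k = sum(unique(.data$gene_id) %in% study),
              .groups = "drop")
  out <- per_term %>%
    mutate(n = n, N = N,
           p = phyper(.data$k - 1, .data$K, N - .data$K, n,
                      lower.tail = FALSE),
           fdr = bh_fdr(.data$p)) %>%
    select("term_id", "k", "n", "K", "N", "p", "fdr") %>%
    arrange(.data$p, .data$term_id)
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper around [stats::p.adjust()] validating the input range;
#' adjusted values are monotone, bounded by 1, elementwise at least the raw
#' p-values, and returned in input order.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric())
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(pvalues, method = "BH")
}

#' Extract a gene-to-term table from a GAF 2.x annotation file
#'
#' Thin column extractor: skips `!` comment lines and keeps the object id
#' (column 2) and term id (column 5) of each association line.
#'
#' @param path Path to the GAF file.
#' @return A deduplicated tibble with columns `gene_id`, `term_id`.
#' @export
read_gaf <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (length(lines) == 0) {
    return(tibble::tibble(gene_id = character(), term_id = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 5)
  if (length(short) > 0) {
    abort(sprintf("GAF line %d has fewer than 5 columns.", short[1]))
  }
  distinct(tibble::tibble(gene_id = vapply(parts, `[[`, "", 2),
                          term_id = vapply(parts, `[[`, "", 5)))
}

#' Read a two-column gene-to-term annotation TSV
#'
#' @param path TSV with columns `gene_id` and `term_id` (header required).
#' @return A deduplicated tibble.
#' @export
read_annotation_table <- function(path) {
  ann <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("gene_id", "term_id") %in% names(ann))) {
    names(ann)[1:2] <- c("gene_id", "term_id")
  }
  distinct(ann[c("gene_id", "term_id")])
}
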