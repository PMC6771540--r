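#' Pairwise gene correlation matrix
#'
#' Pearson correlation between all gene pairs across all samples (of all
#' species jointly when the table spans several species). Zero-variance genes
#' have undefined correlations; these are set to 0 off-diagonal with a
#' warning so downstream network steps treat them as unconnected.
#'
#' @param x An [expr_tbl] (log2 scale recommended) or a numeric
#'   genes-by-samples matrix with row names.
#' @param genes Optional character vector restricting to a gene subset.
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(x, genes = NULL) {
  m <- if (inherits(x, "expr_tbl")) expr_values(x) else as.matrix(x)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing) > 0) {
      abort(sprintf("Unknown gene(s): %s", paste(head(missing, 3), collapse = ", ")))
    }
    m <- m[genes, , drop = FALSE]
  }
  if (ncol(m) < 3) abort("At least 3 samples are required for correlations.")
  sds <- apply(m, 1, sd)
  flat <- sds == 0 | !is.finite(sds)
  r <- suppressWarnings(cor(t(m)))
  if (any(flat)) {
    warn(sprintf("%d zero-variance gene(s); their correlations are set to 0.",
                 sum(flat)))
    r[flat, ] <- 0
    r[, flat] <- 0
  }
  diag(r) <- 1
  r
}

#' Soft-thresholded network adjacency
#'
#' Raises correlations to the soft-thresholding power `beta` to obtain a
#' weighted adjacency: `|r|^beta` for unsigned networks or
#' `((1 + r)/2)^beta` for signed networks. The diagonal is set to 0 (no
#' self-edges). A high power (the default 16) suppresses weak correlations
#' while preserving strong ones, emphasising robust co-expression.
#'
#' @param r Symmetric correlation matrix with entries in \[-1, 1\].
#' @param beta Positive soft-thresholding power (default 16).
#' @param network_type `"unsigned"` (default) or `"signed"`.
#' @return An adjacency matrix with entries in \[0, 1\] and zero diagonal.
#' @export
soft_threshold_adjacency <- function(r, beta = 16,
                                     network_type = c("unsigned", "signed")) {
  network_type <- match.arg(network_type)
  check_square_matrix(r, "r")
  check_number(beta, "beta", lower = .Machine$double.eps)
  if (any(r < -1 - 1e-8 | r > 1 + 1e-8)) {
    abort("Correlations must lie in [-1, 1].")
  }
  a <- if (network_type == "unsigned") abs(r)^beta else ((1 + r) / 2)^beta
  diag(a) <- 0
  a
}

#' Topological overlap of a weighted network
#'
#' The topological overlap measure (TOM) scores two genes as similar when
#' they are directly connected and share neighbours:
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' connectivity `k_i = sum_j a_ij`, and `TOM_ii = 1`. The clustering input is
#' the dissimilarity `1 - TOM`.
#'
#' @param a Symmetric adjacency matrix with zero diagonal and entries in
#'   \[0, 1\], from [soft_threshold_adjacency()].
#' @return A list with `similarity` (TOM) and `dissimilarity` (1 - TOM)
#'   matrices.
#' @export
topological_overlap <- function(a) {
  check_square_matrix(a, "a")
  if (any(a < 0 | a > 1)) abort("Adjacency entries must lie in [0, 1].")
  if (any(diag(a) != 0)) abort("Adjacency diagonal must be 0.")
  k <- rowSums(a)
  shared <- a %*% a  # sum_u a_iu a_uj; the zero diagonal excludes u = i, j
  min_k <- outer(k, k, pmin)
  tom <- (shared + a) / (min_k + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  list(similarity = tom, dissimilarity = 1 - tom)
}

#' Average-linkage hierarchical clustering of a dissimilarity matrix
#'
#' Standard agglomerative clustering where the distance between clusters is
#' the mean pairwise dissimilarity of their members (UPGMA-style), as used on
#' TOM-based dissimilarities.
#'
#' @param d Symmetric dissimilarity matrix with zero diagonal; row names
#'   label the genes.
#' @return An [stats::hclust] dendrogram.
#' @export
average_linkage_cluster <- function(d) {
  check_square_matrix(d, "d")
  if (any(!is.finite(d))) abort("Dissimilarities must be finite.")
  hclust(as.dist(d), method = "average")
}

#' Extract modules from a dendrogram by fractional height cut and minimum size
#'
#' A deterministic tree-cutting rule: the dendrogram is cut at
#' `cut_height_fraction` of its maximum merge height, and every resulting
#' branch with at least `min_module_size` genes becomes a module; smaller
#' branches are pooled into the reserved `"unassigned"` label. Because
#' TOM-based dissimilarities of unrelated genes crowd into a plateau just
#' below their maximum, a cut slightly under that plateau isolates the
#' tight branches while leaving unclustered genes as undersized singleton
#' branches. Modules are labelled `M1`, `M2`, ... in decreasing size (ties
#' broken by first gene index).
#'
#' @param dendrogram An [stats::hclust] object over all genes.
#' @param min_module_size Minimum branch size to form a module (default 30).
#' @param cut_height_fraction Fraction of the maximum merge height at which
#'   to cut (default 0.99).
#' @return A tibble with columns `feature_id` and `module`.
#' @export
dynamic_cut <- function(dendrogram, min_module_size = 30,
                        cut_height_fraction = 0.99) {
  stopifnot(inherits(dendrogram, "hclust"))
  check_number(min_module_size, "min_module_size", lower = 1)
  check_number(cut_height_fraction, "cut_height_fraction",
               lower = .Machine$double.eps, upper = 1)
  cut_h <- cut_height_fraction * max(dendrogram$height)
  # average linkage is monotone, but exact ties can be reordered by
  # floating-point error, which cutree rejects; repair sub-tolerance
  # inversions only
  h <- dendrogram$height
  if (is.unsorted(h)) {
    if (min(diff(h)) < -1e-8 * max(abs(h))) {
      abort("Dendrogram merge heights are not monotone.")
    }
    dendrogram$height <- cummax(h)
  }
  raw <- cutree(dendrogram, h = cut_h)
  relabel_modules(tibble::tibble(feature_id = names(raw),
                                 branch = unname(raw)),
                  min_module_size)
}

# turn raw branch ids into size-ordered module labels with an
# "unassigned" pool for undersized branches
relabel_modules <- function(df, min_module_size) {
  sizes <- df %>%
    mutate(idx = row_number()) %>%
    group_by(.data$branch) %>%
    summarise(size = n(), first_idx = min(.data$idx), .groups = "drop") %>%
    arrange(dplyr::desc(.data$size), .data$first_idx)
  big <- sizes$branch[sizes$size >= min_module_size]
  labels <- setNames(rep("unassigned", nrow(sizes)), sizes$branch)
  labels[as.character(big)] <- paste0("M", seq_along(big))
  tibble::tibble(feature_id = df$feature_id,
                 module = unname(labels[as.character(df$branch)]))
}
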