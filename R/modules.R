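#' Module eigengenes by first principal component
#'
#' Summarises each module by its eigengene: the first principal component of
#' the module's gene-standardised expression (each gene centred and scaled
#' across samples before the decomposition). Eigengenes are unit-norm over
#' samples and sign-oriented to correlate positively with the module's mean
#' standardised profile, removing the sign ambiguity of principal components;
#' when that mean profile is exactly flat (e.g. a module of `x` and `-x`) the
#' orientation follows the module's first gene instead. The variance
#' explained is the leading eigenvalue's share of the module variance.
#'
#' @param x An [expr_tbl] (log2 scale) or genes-by-samples matrix.
#' @param assignments A tibble with columns `feature_id`, `module`; the
#'   reserved label `"unassigned"` is skipped.
#' @return A list with `eigengenes` (modules-by-samples matrix) and
#'   `variance_explained` (named vector in \[0, 1\]).
#' @export
module_eigengenes <- function(x, assignments) {
  m <- if (inherits(x, "expr_tbl")) expr_values(x) else as.matrix(x)
  stopifnot(all(c("feature_id", "module") %in% names(assignments)))
  missing <- setdiff(assignments$feature_id, rownames(m))
  if (length(missing) > 0) {
    abort(sprintf("Assignment refers to unknown gene(s), e.g. %s",
                  paste(head(missing, 3), collapse = ", ")))
  }
  modules <- setdiff(unique(assignments$module), "unassigned")
  if (length(modules) == 0) abort("No modules to summarise.")
  eig <- matrix(NA_real_, nrow = length(modules), ncol = ncol(m),
                dimnames = list(modules, colnames(m)))
  ve <- setNames(numeric(length(modules)), modules)
  for (mod in modules) {
    genes <- assignments$feature_id[assignments$module == mod]
    sub <- m[genes, , drop = FALSE]
    std <- standardise_rows(sub)
    if (nrow(std) == 1) {
      v <- std[1, ]
      nv <- sqrt(sum(v^2))
      eig[mod, ] <- if (nv > 0) v / nv else v
      ve[mod] <- 1
      next
    }
    sv <- svd(std)
    v <- sv$v[, 1]
    ve[mod] <- sv$d[1]^2 / sum(sv$d^2)
    mean_profile <- colMeans(std)
    orient <- sum(v * mean_profile)
    if (abs(orient) < 1e-12) orient <- sum(v * std[1, ])
    if (orient < 0) v <- -v
    eig[mod, ] <- v
  }
  list(eigengenes = eig, variance_explained = ve)
}

standardise_rows <- function(m) {
  ctr <- m - rowMeans(m)
  sds <- sqrt(rowSums(ctr^2) / (ncol(m) - 1))
  sds[sds == 0] <- Inf  # flat genes contribute a zero row
  ctr / sds
}

#' Merge modules with highly correlated eigengenes
#'
#' Iteratively merges the closest pair of modules while their eigengene
#' dissimilarity `1 - Pearson(E_i, E_j)` is below the merge threshold
#' (i.e. correlation above `1 - merge_dissimilarity`), recomputing eigengenes
#' after every merge; the procedure is closest-first and deterministic, and
#' is idempotent on its own output. Final modules are relabelled `M1`,
#' `M2`, ... by decreasing size.
#'
#' @inheritParams module_eigengenes
#' @param merge_dissimilarity Eigengene dissimilarity below which two modules
#'   are merged (default 0.1, i.e. correlation above 0.9).
#' @param params Optional list of network parameters to record in the result.
#' @return A `module_set`: a list with `assignments` (tibble), `eigengenes`,
#'   `variance_explained` and `params`, with `tidy()`, `glance()` and
#'   `autoplot()` methods.
#' @export
merge_modules <- function(x, assignments, merge_dissimilarity = 0.1,
                          params = list()) {
  check_number(merge_dissimilarity, "merge_dissimilarity", lower = 0, upper = 2)
  assignments <- tibble::as_tibble(assignments)[c("feature_id", "module")]
  repeat {
    modules <- setdiff(unique(assignments$module), "unassigned")
    if (length(modules) < 2) break
    me <- module_eigengenes(x, assignments)
    d <- 1 - cor(t(me$eigengenes))
    diag(d) <- Inf
    min_d <- min(d)
    if (min_d >= merge_dissimilarity) break
    idx <- which(d == min_d, arr.ind = TRUE)[1, ]
    from <- rownames(d)[max(idx)]
    into <- rownames(d)[min(idx)]
    assignments$module[assignments$module == from] <- into
  }
  # relabel by decreasing size (ties by first gene index), keep "unassigned"
  sizes <- assignments %>%
    mutate(idx = row_number()) %>%
    filter(.data$module != "unassigned") %>%
    group_by(.data$module) %>%
    summarise(size = n(), first_idx = min(.data$idx), .groups = "drop") %>%
    arrange(dplyr::desc(.data$size), .data$first_idx)
  relabel <- setNames(paste0("M", seq_len(nrow(sizes))), sizes$module)
  relabel["unassigned"] <- "unassigned"
  assignments$module <- unname(relabel[assignments$module])
  me <- module_eigengenes(x, assignments)
  new_module_set(assignments, me$eigengenes, me$variance_explained, params)
}

new_module_set <- function(assignments, eigengenes, variance_explained,
                           params) {
  structure(list(assignments = assignments,
                 eigengenes = eigengenes,
                 variance_explained = variance_explained,
                 params = params),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  sizes <- table(x$assignments$module)
  mods <- setdiff(names(sizes), "unassigned")
  cat(sprintf("Co-expression module set: %d modules over %d genes (%d unassigned)\n",
              length(mods), nrow(x$assignments),
              sum(x$assignments$module == "unassigned")))
  shown <- head(mods, 10)
  cat(sprintf("  %s%s\n",
              paste(sprintf("%s:%d", shown, sizes[shown]), collapse = " "),
              if (length(mods) > 10) " ..." else ""))
  invisible(x)
}

#' @export
tidy.module_set <- function(x, ...) {
  tibble::as_tibble(x$assignments)
}

#' @export
glance.module_set <- function(x, ...) {
  mods <- setdiff(unique(x$assignments$module), "unassigned")
  tibble::tibble(n_modules = length(mods),
                 n_genes = nrow(x$assignments),
                 n_unassigned = sum(x$assignments$module == "unassigned"),
                 median_module_size = stats::median(
                   table(x$assignments$module)[mods]),
                 mean_variance_explained = mean(x$variance_explained))
}

#' Detect co-expression modules from expression data
#'
#' Runs the full weighted co-expression chain: Pearson correlations across
#' all samples, soft-thresholded adjacency, topological-overlap
#' dissimilarity, average-linkage clustering, fractional-height tree cut with a
#' minimum module size, and eigengene-based merging.
#'
#' @param x An [expr_tbl] on the log2 scale (all species' samples jointly for
#'   cross-species analyses), or a genes-by-samples matrix.
#' @param beta Soft-thresholding power (default 16).
#' @param network_type `"unsigned"` (default) or `"signed"`.
#' @param min_module_size Minimum branch size (default 30).
#' @param cut_height_fraction Fraction of the maximum merge height at which the dendrogram
#'   is cut (default 0.99).
#' @param merge_dissimilarity Eigengene dissimilarity below which modules are
#'   merged (default 0.1).
#' @param genes Optional gene subset (e.g. the EMO genes).
#' @param top_n_variable Optional cap: keep only the `top_n_variable` most
#'   variable genes before network construction.
#' @return A `module_set` (see [merge_modules()]).
#' @export
detect_modules <- function(x, beta = 16,
                           network_type = c("unsigned", "signed"),
                           min_module_size = 30, cut_height_fraction = 0.99,
                           merge_dissimilarity = 0.1, genes = NULL,
                           top_n_variable = NULL) {
  network_type <- match.arg(network_type)
  m <- if (inherits(x, "expr_tbl")) expr_values(x) else as.matrix(x)
  if (!is.null(genes)) m <- m[intersect(genes, rownames(m)), , drop = FALSE]
  if (!is.null(top_n_variable) && top_n_variable < nrow(m)) {
    vars <- apply(m, 1, stats::var)
    m <- m[order(vars, decreasing = TRUE)[seq_len(top_n_variable)], ,
           drop = FALSE]
  }
  params <- list(beta = beta, network_type = network_type,
                 min_module_size = min_module_size,
                 cut_height_fraction = cut_height_fraction,
                 merge_dissimilarity = merge_dissimilarity,
                 n_genes = nrow(m), n_samples = ncol(m))
  r <- correlation_matrix(m)
  a <- soft_threshold_adjacency(r, beta = beta, network_type = network_type)
  tom <- topological_overlap(a)
  dendro <- average_linkage_cluster(tom$dissimilarity)
  raw <- dynamic_cut(dendro, min_module_size = min_module_size,
                     cut_height_fraction = cut_height_fraction)
  if (all(raw$module == "unassigned")) {
    return(new_module_set(raw,
                          eigengenes = matrix(numeric(), 0, ncol(m),
                                              dimnames = list(NULL, colnames(m))),
                          variance_explained = setNames(numeric(), character()),
                          params = params))
  }
  merge_modules(m, raw, merge_dissimilarity = merge_dissimilarity,
                params = params)
}

#' Numeric trait encoding of sample annotations
#'
#' Encodes the sample annotations as numeric traits for module-trait
#' correlation: one indicator column per species, a water-deficit indicator
#' (`treatment_wd`, WD = 1), and the timepoint rank (`timepoint_rank`).
#'
#' @param sample_info A sample-annotation tibble (see [expr_tbl]).
#' @return A tibble with `sample_id` plus one numeric column per trait.
#' @export
build_trait_matrix <- function(sample_info) {
  si <- sample_info
  out <- tibble::tibble(sample_id = si$sample_id)
  for (sp in unique(si$species)) {
    out[[paste0("species_", sp)]] <- as.numeric(si$species == sp)
  }
  out$treatment_wd <- as.numeric(si$condition == "WD")
  out$timepoint_rank <- as.numeric(as.integer(si$timepoint))
  out
}

#' Correlate module eigengenes with sample traits
#'
#' Pearson correlation of each module eigengene with each numeric trait,
#' with a two-sided p-value from the t distribution on `n - 2` degrees of
#' freedom and Benjamini-Hochberg adjustment across the whole
#' module-by-trait family. Constant traits have undefined correlations and
#' are reported as `NA` (excluded from the adjustment family).
#'
#' @param x A `module_set` or an eigengene matrix (modules by samples).
#' @param traits A tibble from [build_trait_matrix()] (or any tibble with
#'   `sample_id` plus numeric trait columns covering the eigengene samples).
#' @param fdr_level Significance threshold on the adjusted values
#'   (default 0.05; 0.1 is a common lenient alternative).
#' @return A tibble with columns `module`, `trait`, `r`, `p`, `fdr`,
#'   `significant`.
#' @export
module_trait_correlation <- function(x, traits, fdr_level = 0.05) {
  eig <- if (inherits(x, "module_set")) x$eigengenes else as.matrix(x)
  check_number(fdr_level, "fdr_level", lower = 0, upper = 1)
  traits <- tibble::as_tibble(traits)
  stopifnot("sample_id" %in% names(traits))
  idx <- match(colnames(eig), traits$sample_id)
  if (anyNA(idx)) abort("Traits must cover every eigengene sample.")
  tmat <- as.matrix(traits[idx, setdiff(names(traits), "sample_id")])
  n <- ncol(eig)
  out <- tidyr::expand_grid(module = rownames(eig), trait = colnames(tmat))
  stat <- purrr::map2(out$module, out$trait, function(mod, tr) {
    tv <- tmat[, tr]
    if (sd(tv) == 0 || sd(eig[mod, ]) == 0) {
      return(c(r = NA_real_, p = NA_real_))
    }
    r <- cor(eig[mod, ], tv)
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    c(r = r, p = 2 * pt(-abs(tstat), df = n - 2))
  })
  out$r <- purrr::map_dbl(stat, "r")
  out$p <- purrr::map_dbl(stat, "p")
  out$fdr <- NA_real_
  ok <- !is.na(out$p)
  out$fdr[ok] <- p.adjust(out$p[ok], method = "BH")
  out$significant <- !is.na(out$fdr) & out$fdr < fdr_level
  if (any(!ok)) {
    inform(sprintf("%d module-trait pair(s) with constant input reported as NA.",
                   sum(!ok)))
  }
  out
}
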