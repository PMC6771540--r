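#' Permutation test for multi-species overlap of regulated orthologs
#'
#' Assesses whether the number of orthologs regulated in every species is
#' larger than expected by chance. In each permutation, a gene set of the
#' observed size is drawn for each species uniformly without replacement from
#' the common-ortholog background, and the size of the full intersection is
#' recorded. The empirical p-value is the fraction of permutations whose null
#' overlap is greater than or equal to the observed overlap; when no
#' permutation reaches it the p-value is reported as below `1/n`.
#'
#' @param background Character vector of background ids (the common-ortholog
#'   universe), or a single integer giving its size.
#' @param set_sizes Integer vector (one per species) of regulated-set sizes;
#'   each must not exceed the background size.
#' @param observed The observed size of the full intersection; must not
#'   exceed the smallest set size.
#' @param n Number of permutations (default 1000).
#' @param seed Integer seed for the permutation stream; recorded in the
#'   result so it can be reproduced.
#' @return An object of class `overlap_permutation` with the observed
#'   overlap, exceedance count, p-value (and display string), null mean/sd,
#'   the full null distribution, and the seed. `glance()` gives a one-row
#'   tibble; `autoplot()` draws the null distribution.
#' @export
#' @examples
#' permutation_overlap_test(100, c(20, 25, 30), observed = 5, seed = 1)
permutation_overlap_test <- function(background, set_sizes, observed,
                                     n = 1000, seed = NULL) {
  n_background <- if (length(background) == 1 && is.numeric(background)) {
    as.integer(background)
  } else {
    length(unique(background))
  }
  if (n_background < 1) abort("Empty background.")
  set_sizes <- as.integer(set_sizes)
  if (length(set_sizes) < 2) {
    abort("`set_sizes` needs at least two species.")
  }
  if (any(set_sizes < 0) || any(set_sizes > n_background)) {
    abort("Each set size must be between 0 and the background size.")
  }
  check_number(observed, "observed", lower = 0, upper = min(set_sizes))
  check_number(n, "n", lower = 1)
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  k <- length(set_sizes)
  null_overlap <- integer(n)
  for (i in seq_len(n)) {
    tallies <- integer(n_background)
    for (j in seq_len(k)) {
      picked <- sample.int(n_background, set_sizes[j])
      tallies[picked] <- tallies[picked] + 1L
    }
    null_overlap[i] <- sum(tallies == k)
  }
  n_ge <- sum(null_overlap >= observed)
  p <- n_ge / n
  p_text <- if (n_ge == 0) {
    sprintf("p < 1/%d", n)
  } else {
    sprintf("p = %d/%d", n_ge, n)
  }
  structure(list(observed_overlap = as.integer(observed),
                 n_permutations = n,
                 n_ge_observed = n_ge,
                 p = p,
                 p_text = p_text,
                 null_mean = mean(null_overlap),
                 null_sd = sd(null_overlap),
                 null_overlap = null_overlap,
                 set_sizes = set_sizes,
                 n_background = n_background,
                 seed = seed),
            class = "overlap_permutation")
}

#' @export
print.overlap_permutation <- function(x, ...) {
  cat("Permutation test for multi-set overlap\n")
  cat(sprintf("  background: %d ids; set sizes: %s\n", x$n_background,
              paste(x$set_sizes, collapse = ", ")))
  cat(sprintf("  observed overlap: %d; null mean %.3f (sd %.3f) over %d permutations\n",
              x$observed_overlap, x$null_mean, x$null_sd, x$n_permutations))
  cat(sprintf("  %s\n", x$p_text))
  invisible(x)
}

#' @export
glance.overlap_permutation <- function(x, ...) {
  tibble::tibble(observed_overlap = x$observed_overlap,
                 n_permutations = x$n_permutations,
                 n_ge_observed = x$n_ge_observed,
                 p = x$p,
                 p_text = x$p_text,
                 null_mean = x$null_mean,
                 null_sd = x$null_sd,
                 seed = if (is.null(x$seed)) NA_integer_ else x$seed)
}

#' @export
tidy.overlap_permutation <- function(x, ...) {
  tibble::tibble(permutation = seq_along(x$null_overlap),
                 null_overlap = x$null_overlap)
}

#' @rdname permutation_overlap_test
#' @param object An `overlap_permutation` result.
#' @param ... Unused.
#' @export
autoplot.overlap_permutation <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null_overlap)) +
    ggplot2::geom_bar(fill = "grey60") +
    ggplot2::geom_vline(xintercept = object$observed_overlap,
                        colour = "firebrick", linetype = 2) +
    ggplot2::labs(x = "null overlap size", y = "permutations",
                  title = "Permutation null for multi-species overlap",
                  subtitle = object$p_text) +
    ggplot2::theme_minimal()
}
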