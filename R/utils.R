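#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items, used to
#' score recovered co-expression module assignments against planted ground
#' truth. Labels are arbitrary; only the induced partitions matter.
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return A single number; 1 for identical partitions, about 0 for random
#'   agreement.
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b"))
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) {
    abort("`a` and `b` must label the same items (equal length).")
  }
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) {
    return(1)
  }
  (sum_ij - expected) / (max_index - expected)
}

# shared input checks -------------------------------------------------------

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name, lower, upper, x))
  }
  invisible(x)
}

check_square_matrix <- function(m, name, symmetric = TRUE) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    abort(sprintf("`%s` must be a square matrix.", name))
  }
  if (symmetric && !isTRUE(all.equal(m, t(m), tolerance = 1e-8,
                                     check.attributes = FALSE))) {
    abort(sprintf("`%s` must be symmetric.", name))
  }
  invisible(m)
}
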