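# in-code fixtures and independent oracles used across the suite

toy_metadata <- function(species = "Ath",
                         conditions = c("WW", "WD"),
                         timepoints = c("T0", "T5", "T11", "T14"),
                         replicates = 1:3) {
  grid <- expand.grid(replicate = replicates, timepoint = timepoints,
                      condition = conditions, species = species,
                      stringsAsFactors = FALSE)
  tibble::tibble(
    sample_id = sprintf("%s_%s_%s_R%d", grid$species, grid$condition,
                        grid$timepoint, grid$replicate),
    species = grid$species, condition = grid$condition,
    timepoint = grid$timepoint, replicate = grid$replicate)
}

toy_expr <- function(values, metadata, scale = "tpm",
                     feature_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(feature_ids)) {
    feature_ids <- sprintf("g%03d", seq_len(nrow(values)))
  }
  df <- tibble::as_tibble(values, .name_repair = "minimal")
  names(df) <- metadata$sample_id[seq_len(ncol(values))]
  df <- tibble::add_column(df, feature_id = feature_ids, .before = 1)
  expr_tbl(df, metadata[seq_len(ncol(values)), ], scale = scale)
}

# brute-force TOM by the defining triple loop
brute_force_tom <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      s <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) s <- s + a[i, u] * a[u, j]
      }
      tom[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  tom
}

# exhaustive reciprocal-best-hit oracle: for every candidate pair check the
# mutual-best property directly against all hits, with the tie-break chain
brute_force_rbh <- function(ab, ba) {
  better <- function(h1, h2) {
    # is h1 strictly better than h2?
    if (h1$bitscore != h2$bitscore) return(h1$bitscore > h2$bitscore)
    if (h1$evalue != h2$evalue) return(h1$evalue < h2$evalue)
    if (h1$pident != h2$pident) return(h1$pident > h2$pident)
    h1$sseqid < h2$sseqid
  }
  best_of <- function(hits, q) {
    rows <- hits[hits$qseqid == q, ]
    if (nrow(rows) == 0) return(NULL)
    b <- rows[1, ]
    for (i in seq_len(nrow(rows))[-1]) {
      if (better(rows[i, ], b)) b <- rows[i, ]
    }
    b
  }
  pairs <- list()
  for (q in unique(ab$qseqid)) {
    b1 <- best_of(ab, q)
    b2 <- best_of(ba, b1$sseqid)
    if (!is.null(b2) && b2$sseqid == q) {
      pairs[[length(pairs) + 1]] <-
        tibble::tibble(species_a_gene = q, species_b_gene = b1$sseqid)
    }
  }
  out <- dplyr::bind_rows(pairs)
  out[order(out$species_a_gene), ]
}

# step-up false-discovery-rate oracle, straight from the definition
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  sorted <- p[ord]
  adj <- sorted * m / seq_len(m)
  # enforce monotonicity from the largest rank down
  for (i in rev(seq_len(m - 1))) {
    adj[i] <- min(adj[i], adj[i + 1])
  }
  q[ord] <- pmin(adj, 1)
  q
}

# exhaustive overlap-permutation oracle for tiny backgrounds: enumerate all
# equally likely per-species subsets and count the exceedance probability
exact_overlap_p <- function(n_background, set_sizes, observed) {
  choices <- lapply(set_sizes, function(s) {
    utils::combn(n_background, s, simplify = FALSE)
  })
  grids <- expand.grid(lapply(choices, seq_along))
  hits <- 0
  for (r in seq_len(nrow(grids))) {
    sets <- lapply(seq_along(choices), function(j) {
      choices[[j]][[grids[r, j]]]
    })
    if (length(Reduce(intersect, sets)) >= observed) hits <- hits + 1
  }
  hits / nrow(grids)
}
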