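#' Read protein similarity hits in 12-column tabular format
#'
#' Parses the standard tab-separated similarity-search output (qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue bitscore)
#' and applies the E-value cutoff used for orthology calling. The cutoff is
#' inclusive and row order is preserved.
#'
#' @param path Path to the tabular hits file (no header).
#' @param max_evalue Hits with E-value above this are discarded
#'   (default 1e-3).
#' @return A tibble of hits with the 12 standard columns.
#' @export
read_blast_tab <- function(path, max_evalue = 1e-3) {
  check_number(max_evalue, "max_evalue", lower = 0)
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    out <- tibble::as_tibble(setNames(
      c(list(character(), character()), rep(list(numeric()), 10)), cols))
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(parts)
  if (any(n_fields != 12)) {
    bad <- which(n_fields != 12)[1]
    abort(sprintf("Malformed hits line %d in %s: expected 12 fields, found %d",
                  bad, path, n_fields[bad]))
  }
  m <- matrix(unlist(parts), ncol = 12, byrow = TRUE)
  out <- tibble::tibble(qseqid = m[, 1], sseqid = m[, 2])
  for (j in 3:12) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      abort(sprintf("Malformed hits line %d in %s: non-numeric '%s' in column %s",
                    bad, path, m[bad, j], cols[j]))
    }
    out[[cols[j]]] <- v
  }
  filter(out, .data$evalue <= max_evalue)
}

best_hit_per_query <- function(hits) {
  # best = max bitscore, ties by min evalue, then max pident, then
  # lexicographically smallest subject id: a fully deterministic chain
  hits %>%
    arrange(.data$qseqid, dplyr::desc(.data$bitscore), .data$evalue,
            dplyr::desc(.data$pident), .data$sseqid) %>%
    group_by(.data$qseqid) %>%
    dplyr::slice(1) %>%
    ungroup()
}

#' Reciprocal-best-hit ortholog pairs
#'
#' A gene pair (g, h) is called orthologous when h is g's best hit in the
#' forward search and g is h's best hit in the reverse search. "Best" is the
#' maximum bitscore, with ties broken by minimum E-value, then maximum percent
#' identity, then lexicographic subject id, so the result is deterministic.
#' Each gene occurs in at most one pair (one-to-one).
#'
#' @param ab Hits with species-A queries and species-B subjects, as returned
#'   by [read_blast_tab()].
#' @param ba Hits in the reverse direction.
#' @return A tibble with columns `species_a_gene`, `species_b_gene`,
#'   `bitscore_ab`, `bitscore_ba`.
#' @export
reciprocal_best_hits <- function(ab, ba) {
  best_ab <- best_hit_per_query(ab)
  best_ba <- best_hit_per_query(ba)
  pairs <- inner_join(
    select(best_ab, species_a_gene = "qseqid", species_b_gene = "sseqid",
           bitscore_ab = "bitscore"),
    select(best_ba, species_b_gene = "qseqid", species_a_gene = "sseqid",
           bitscore_ba = "bitscore"),
    by = c("species_a_gene", "species_b_gene"))
  arrange(pairs, .data$species_a_gene)
}

#' Assemble expressed-mutual-ortholog (EMO) triples
#'
#' Combines the three pairwise one-to-one ortholog tables into
#' one-to-one-to-one triples. A triple (a, b, c) is kept when the (a, b) and
#' (a, c) pairs exist, the (b, c) edge closes the triangle consistently, and
#' all three genes pass the expression filter in their species. Triangles
#' whose third edge points elsewhere are dropped and counted in the
#' `"n_inconsistent"` attribute.
#'
#' @param ab,ac,bc Pair tables from [reciprocal_best_hits()] for species
#'   pairs (A,B), (A,C) and (B,C).
#' @param expressed A list of three character vectors of expressed gene ids,
#'   in species order A, B, C. Use `NULL` to skip the expression restriction.
#' @param species Names for the three species (column names of the result).
#' @param closure `"strict"` requires all three edges to agree (guaranteeing
#'   one-to-one-to-one triples); `"two_edge"` keeps triples whose (b, c) edge
#'   is merely absent rather than contradictory.
#' @return A tibble of triples, one column per species, with attributes
#'   `n_inconsistent` (contradictory triangles dropped) and `provenance`.
#' @export
build_emo_table <- function(ab, ac, bc, expressed = NULL,
                            species = c("Ath", "Aly", "Esa"),
                            closure = c("strict", "two_edge")) {
  closure <- match.arg(closure)
  stopifnot(length(species) == 3)
  cand <- inner_join(
    select(ab, a = "species_a_gene", b = "species_b_gene"),
    select(ac, a = "species_a_gene", c = "species_b_gene"),
    by = "a")
  bc_map_b <- setNames(bc$species_b_gene, bc$species_a_gene)  # b -> c
  bc_map_c <- setNames(bc$species_a_gene, bc$species_b_gene)  # c -> b
  partner_of_b <- unname(bc_map_b[cand$b])
  partner_of_c <- unname(bc_map_c[cand$c])
  consistent <- !is.na(partner_of_b) & partner_of_b == cand$c
  edge_absent <- is.na(partner_of_b) & is.na(partner_of_c)
  inconsistent <- !consistent & !edge_absent
  keep <- if (closure == "strict") consistent else consistent | edge_absent
  out <- cand[keep, ]
  if (!is.null(expressed)) {
    stopifnot(length(expressed) == 3)
    out <- filter(out,
                  .data$a %in% expressed[[1]] &
                    .data$b %in% expressed[[2]] &
                    .data$c %in% expressed[[3]])
  }
  names(out) <- species
  out <- tibble::as_tibble(out)
  attr(out, "n_inconsistent") <- sum(inconsistent)
  attr(out, "provenance") <- list(closure = closure,
                                  expressed_restricted = !is.null(expressed))
  out
}

#' Write an EMO table as a three-column TSV
#'
#' @param emo A triple table from [build_emo_table()].
#' @param path Output path.
#' @return `emo`, invisibly.
#' @export
write_emo_table <- function(emo, path) {
  readr::write_tsv(tibble::as_tibble(emo), path, progress = FALSE)
  invisible(emo)
}
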