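hit_line <- function(q, s, bit, ev = 1e-20, pid = 80) {
  paste(q, s, pid, 200, 10, 1, 1, 200, 1, 200,
        format(ev, scientific = TRUE), bit, sep = "\t")
}

test_that("tabular hits parse with an inclusive E-value cutoff", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(hit_line("a1", "b1", 500, ev = 1e-2),
               hit_line("a2", "b2", 400, ev = 1e-3),
               hit_line("a3", "b3", 300, ev = 1e-9)), path)
  hits <- read_blast_tab(path)
  expect_equal(hits$qseqid, c("a2", "a3"))  # 1e-2 excluded, 1e-3 kept

  writeLines(character(), path)
  expect_equal(nrow(read_blast_tab(path)), 0)

  writeLines(c(hit_line("a1", "b1", 500), "broken\tline"), path)
  expect_error(read_blast_tab(path), "line 2")
})

test_that("reciprocal best hits require mutual top scores", {
  ab <- tibble::tibble(qseqid = c("g1", "g1"), sseqid = c("h1", "h2"),
                       pident = 80, length = 100, mismatch = 5, gapopen = 0,
                       qstart = 1, qend = 100, sstart = 1, send = 100,
                       evalue = 1e-50, bitscore = c(200, 150))
  ba <- ab[1, ]
  ba$qseqid <- "h1"; ba$sseqid <- "g1"; ba$bitscore <- 198
  pairs <- reciprocal_best_hits(ab, ba)
  expect_equal(pairs$species_a_gene, "g1")
  expect_equal(pairs$species_b_gene, "h1")
  expect_equal(pairs$bitscore_ab, 200)

  # asymmetric best hits produce no pair
  ba$sseqid <- "g2"
  expect_equal(nrow(reciprocal_best_hits(ab, ba)), 0)
})

test_that("RBH matches the exhaustive oracle on random hit tables", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 5
    genes_a <- paste0("a", 1:n)
    genes_b <- paste0("b", 1:n)
    grid <- expand.grid(qseqid = genes_a, sseqid = genes_b,
                        stringsAsFactors = FALSE)
    grid <- grid[runif(nrow(grid)) < 0.7, ]
    make <- function(g) {
      tibble::tibble(qseqid = g$qseqid, sseqid = g$sseqid,
                     pident = round(runif(nrow(g), 50, 99), 1),
                     length = 100, mismatch = 1, gapopen = 0, qstart = 1,
                     qend = 100, sstart = 1, send = 100,
                     evalue = 10^-sample(5:50, nrow(g), replace = TRUE),
                     bitscore = sample(100:120, nrow(g), replace = TRUE))
    }
    ab <- make(grid)
    ba <- make(setNames(grid[2:1], c("qseqid", "sseqid")))
    got <- reciprocal_best_hits(ab, ba)
    expected <- brute_force_rbh(ab, ba)
    expect_equal(got[c("species_a_gene", "species_b_gene")],
                 expected, ignore_attr = TRUE)
  }
})

test_that("EMO triples require closed triangles and expression", {
  pair <- function(a, b) {
    tibble::tibble(species_a_gene = a, species_b_gene = b,
                   bitscore_ab = 100, bitscore_ba = 100)
  }
  ab <- pair("a1", "b1"); ac <- pair("a1", "c1"); bc <- pair("b1", "c1")
  expressed <- list(c("a1"), c("b1"), c("c1"))
  emo <- build_emo_table(ab, ac, bc, expressed)
  expect_equal(nrow(emo), 1)
  expect_equal(unlist(emo[1, ], use.names = FALSE), c("a1", "b1", "c1"))
  expect_equal(attr(emo, "n_inconsistent"), 0)

  # one unexpressed member removes the triple
  emo <- build_emo_table(ab, ac, bc, list("a1", "b1", character()))
  expect_equal(nrow(emo), 0)

  # third edge pointing elsewhere is counted as inconsistent
  emo <- build_emo_table(ab, ac, pair("b1", "c9"), expressed)
  expect_equal(nrow(emo), 0)
  expect_equal(attr(emo, "n_inconsistent"), 1)

  # absent third edge: dropped under strict closure, kept under two_edge
  none <- pair(character(), character())
  expect_equal(nrow(build_emo_table(ab, ac, none, expressed)), 0)
  expect_equal(nrow(build_emo_table(ab, ac, none, expressed,
                                    closure = "two_edge")), 1)
})

test_that("EMO assembly is invariant to row order and is one-to-one", {
  sim <- simulate_expression(simulation_config(
    seed = 21, n_genes = 80, module_sizes = integer(),
    module_traits = character(), n_responders = 10))
  orth <- simulate_orthology(sim$truth$ortho, decoy_rate = 0.3, seed = 22)
  rbh_of <- function(a, b) {
    reciprocal_best_hits(orth$hits[[sprintf("%s_vs_%s", a, b)]],
                         orth$hits[[sprintf("%s_vs_%s", b, a)]])
  }
  ab <- rbh_of("Ath", "Aly"); ac <- rbh_of("Ath", "Esa")
  bc <- rbh_of("Aly", "Esa")
  emo <- build_emo_table(ab, ac, bc)
  set.seed(1)
  shuffled <- build_emo_table(ab[sample(nrow(ab)), ],
                              ac[sample(nrow(ac)), ],
                              bc[sample(nrow(bc)), ])
  expect_equal(dplyr::arrange(tibble::as_tibble(emo), Ath),
               dplyr::arrange(tibble::as_tibble(shuffled), Ath))
  expect_false(any(duplicated(unlist(emo))))
})

test_that("planted orthology is recovered perfectly despite decoys", {
  sim <- simulate_expression(simulation_config(
    seed = 23, n_genes = 100, module_sizes = integer(),
    module_traits = character(), n_responders = 0))
  orth <- simulate_orthology(sim$truth$ortho, decoy_rate = 0.2,
                             missing_rate = 0, seed = 24)
  rbh_of <- function(a, b) {
    reciprocal_best_hits(orth$hits[[sprintf("%s_vs_%s", a, b)]],
                         orth$hits[[sprintf("%s_vs_%s", b, a)]])
  }
  emo <- build_emo_table(rbh_of("Ath", "Aly"), rbh_of("Ath", "Esa"),
                         rbh_of("Aly", "Esa"))
  expect_equal(dplyr::arrange(tibble::as_tibble(emo), Ath),
               dplyr::arrange(orth$triples, Ath), ignore_attr = TRUE)
})
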