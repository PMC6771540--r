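#' Configuration for the synthetic drought-course study
#'
#' Bundles every knob of the synthetic-data generators. The defaults emulate
#' the study design the pipeline targets: 3 Brassicaceae species x 2
#' watering conditions (WW, WD) x 4 timepoints (T0, T5, T11, T14) x 3
#' biological replicates of TPM-scaled transcript abundances, with planted
#' co-expression modules, planted per-species induction timing, a planted
#' one-to-one orthology and rosette growth trajectories.
#'
#' @param seed Integer seed; every generator draw derives from it.
#' @param species Species labels (default Ath, Aly, Esa).
#' @param timepoints Ordered timepoint labels; the first is the pre-stress
#'   baseline.
#' @param n_replicates Biological replicates per condition x timepoint.
#' @param n_genes Genes per species.
#' @param ortho_fraction Fraction of genes in one-to-one ortholog triples
#'   (matched by index across species).
#' @param transcripts_range Inclusive range of transcripts per gene; gene
#'   TPM is split among transcripts by Dirichlet weights.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of baseline
#'   gene TPM.
#' @param module_sizes Sizes of the planted co-expressed modules (drawn from
#'   the ortholog genes, so module signals are shared across species).
#' @param module_cor Latent-signal share of module-gene variance: the
#'   within-module correlation of the noiseless profiles.
#' @param module_signal_sd Standard deviation (log2 units) of the module
#'   expression signal.
#' @param module_traits One trait per module to leak into its latent signal:
#'   `"treatment"`, `"timepoint"`, `"species:<name>"` or `"none"`.
#' @param trait_assoc_strength Scale of the trait component added to module
#'   latent signals.
#' @param n_responders Drought-induced genes per species (disjoint from
#'   module genes).
#' @param responder_effect_range Range of planted peak log2 fold changes.
#' @param secondary_peak_factor Fold-change multiplier at induced timepoints
#'   other than the highest peak (default 0.9 keeps them clearly induced yet
#'   below the peak).
#' @param noise_sd Replicate noise standard deviation on the log2(TPM+1)
#'   scale; 0 gives noiseless data.
#' @param decoy_rate Probability that a true ortholog pair gains a
#'   lower-scoring paralog decoy hit per search direction.
#' @param missing_rate Probability that a true pair is absent from a
#'   pairwise search.
#' @param growth A list of rosette-growth settings; see
#'   [simulate_growth()].
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1,
                              species = c("Ath", "Aly", "Esa"),
                              timepoints = c("T0", "T5", "T11", "T14"),
                              n_replicates = 3,
                              n_genes = 600,
                              ortho_fraction = 0.8,
                              transcripts_range = c(1, 4),
                              baseline_meanlog = 1.5,
                              baseline_sdlog = 1.2,
                              module_sizes = c(60, 60, 60, 60),
                              module_cor = 0.8,
                              module_signal_sd = 2,
                              module_traits = c("treatment", "timepoint",
                                                "species:Esa", "none"),
                              trait_assoc_strength = 1,
                              n_responders = 120,
                              responder_effect_range = c(1.5, 4),
                              secondary_peak_factor = 0.9,
                              noise_sd = 0.2,
                              decoy_rate = 0.2,
                              missing_rate = 0,
                              growth = list()) {
  cfg <- list(seed = as.integer(seed), species = species,
              timepoints = timepoints, n_replicates = as.integer(n_replicates),
              n_genes = as.integer(n_genes), ortho_fraction = ortho_fraction,
              transcripts_range = as.integer(transcripts_range),
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog,
              module_sizes = as.integer(module_sizes),
              module_cor = module_cor,
              module_signal_sd = module_signal_sd,
              module_traits = module_traits,
              trait_assoc_strength = trait_assoc_strength,
              n_responders = as.integer(n_responders),
              responder_effect_range = responder_effect_range,
              secondary_peak_factor = secondary_peak_factor,
              noise_sd = noise_sd, decoy_rate = decoy_rate,
              missing_rate = missing_rate,
              growth = utils::modifyList(default_growth_params(species),
                                         growth))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

default_growth_params <- function(species = c("Ath", "Aly", "Esa")) {
  named_or_recycled <- function(values, default) {
    out <- setNames(rep(default, length(species)), species)
    common <- intersect(names(values), species)
    out[common] <- values[common]
    out
  }
  list(days = 0:14,
       n_plants_per_replicate = 27L,
       n_replicates = 3L,
       # starting rosette areas (mm^2) and response onsets typical of the
       # three species at matched developmental stage
       area0 = named_or_recycled(c(Ath = 100, Aly = 211, Esa = 94), 100),
       divergence_day = named_or_recycled(c(Ath = 5, Aly = 3, Esa = 6), 5),
       survival_prob = named_or_recycled(c(Ath = 0.76, Aly = 0.96, Esa = 0.98),
                                         0.9),
       growth_rate = 0.18,
       capacity = 8000,
       wd_rate_factor = 0.25,
       noise_sd = 0.05,
       plant_sd = 0.1,
       stockiness_range = c(0.15, 0.45),
       compactness_range = c(0.55, 0.9))
}

validate_simulation_config <- function(cfg) {
  problems <- character()
  add <- function(msg) problems <<- c(problems, msg)
  if (length(cfg$species) < 1) add("at least one species is required")
  if (length(cfg$timepoints) < 2) add("at least two timepoints are required")
  if (cfg$n_replicates < 1) add("n_replicates must be positive")
  if (cfg$n_genes < 1) add("n_genes must be positive")
  for (fld in c("ortho_fraction", "module_cor", "decoy_rate",
                "missing_rate")) {
    v <- cfg[[fld]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      add(sprintf("%s must lie in [0, 1]", fld))
    }
  }
  if (cfg$noise_sd < 0) add("noise_sd must be nonnegative")
  n_ortho <- floor(cfg$ortho_fraction * cfg$n_genes)
  if (sum(cfg$module_sizes) > n_ortho) {
    add("module genes must fit within the ortholog set")
  }
  if (length(cfg$module_traits) != length(cfg$module_sizes)) {
    add("module_traits must name one trait per module")
  }
  if (sum(cfg$module_sizes) + cfg$n_responders > cfg$n_genes) {
    add("module and responder genes together exceed n_genes")
  }
  if (any(cfg$transcripts_range < 1) ||
      cfg$transcripts_range[2] < cfg$transcripts_range[1]) {
    add("transcripts_range must be an increasing pair of positive integers")
  }
  if (length(problems) > 0) {
    abort(paste0("Invalid simulation config:\n",
                 paste0("- ", problems, collapse = "\n")))
  }
  invisible(cfg)
}

sample_table <- function(sp, cfg) {
  grid <- expand.grid(replicate = seq_len(cfg$n_replicates),
                      timepoint = cfg$timepoints,
                      condition = c("WW", "WD"),
                      stringsAsFactors = FALSE)
  tibble::tibble(
    sample_id = sprintf("%s_%s_%s_R%d", sp, grid$condition, grid$timepoint,
                        grid$replicate),
    species = sp,
    condition = grid$condition,
    timepoint = grid$timepoint,
    replicate = grid$replicate)
}

module_trait_vector <- function(trait, joint_si) {
  n <- nrow(joint_si)
  if (trait == "none") return(rep(0, n))
  if (trait == "treatment") return(as.numeric(joint_si$condition == "WD"))
  if (trait == "timepoint") {
    return(as.numeric(match(joint_si$timepoint,
                            unique(joint_si$timepoint))))
  }
  if (startsWith(trait, "species:")) {
    sp <- sub("^species:", "", trait)
    return(as.numeric(joint_si$species == sp))
  }
  abort(sprintf("Unknown module trait '%s'.", trait))
}

#' Simulate a multi-species drought RNA-seq time course
#'
#' Generates transcript-level TPM tables with sample annotations for each
#' species, together with the full ground truth. Baseline gene abundances
#' are log-normal (shared across species for ortholog triples); planted
#' module genes share a latent signal at the configured within-module
#' correlation across the joint samples of all species; planted responders
#' gain their log2 fold change in the water-deficit arm from their first
#' induced timepoint onward, peaking at their highest-peak timepoint, with
#' the effect applied on the log2(TPM+1) scale so that with zero noise the
#' replicate-mean pseudocount fold change equals the planted value exactly.
#' Gene TPM is split into transcripts by per-gene Dirichlet weights.
#' Deterministic under the config seed.
#'
#' @param cfg A [simulation_config()].
#' @return A list of class `drought_sim` with elements `species_data` (per
#'   species: `tpm` transcript-level [expr_tbl], `tx2gene`, `metadata`),
#'   `truth` (module assignments and latent signals, responder peaks,
#'   planted fold-change profiles, ortholog triples) and `config`.
#' @export
simulate_expression <- function(cfg = simulation_config()) {
  validate_simulation_config(cfg)
  set.seed(cfg$seed)
  species <- cfg$species
  tps <- cfg$timepoints
  post_tps <- tps[-1]
  n_genes <- cfg$n_genes
  n_ortho <- floor(cfg$ortho_fraction * n_genes)

  sample_tables <- lapply(species, sample_table, cfg = cfg)
  names(sample_tables) <- species
  joint_si <- bind_rows(sample_tables)
  n_per_sp <- nrow(sample_tables[[1]])
  sp_span <- function(sp) {
    which(joint_si$species == sp)
  }

  gene_ids <- lapply(species, function(sp) sprintf("%sg%04d", sp, seq_len(n_genes)))
  names(gene_ids) <- species

  # baselines: ortholog genes share a baseline across species
  base_ortho <- rlnorm(n_ortho, cfg$baseline_meanlog, cfg$baseline_sdlog)
  base <- lapply(species, function(sp) {
    c(base_ortho, rlnorm(n_genes - n_ortho, cfg$baseline_meanlog,
                         cfg$baseline_sdlog))
  })
  names(base) <- species

  # joint log2(TPM + 1) signal matrix: genes x all samples of all species
  log2ps <- matrix(0, nrow = n_genes, ncol = nrow(joint_si))
  for (sp in species) {
    log2ps[, sp_span(sp)] <- log2(base[[sp]] + 1)
  }

  # planted modules over ortholog genes, shared latent across species
  module_assign <- rep("unassigned", n_genes)
  n_modules <- length(cfg$module_sizes)
  latents <- matrix(NA_real_, nrow = n_modules, ncol = nrow(joint_si),
                    dimnames = list(if (n_modules > 0)
                      paste0("module", seq_len(n_modules)) else NULL,
                      joint_si$sample_id))
  offset <- 0
  for (mi in seq_len(n_modules)) {
    size <- cfg$module_sizes[mi]
    members <- offset + seq_len(size)
    offset <- offset + size
    module_assign[members] <- paste0("module", mi)
    z <- rnorm(nrow(joint_si))
    tv <- module_trait_vector(cfg$module_traits[mi], joint_si)
    if (sd(tv) > 0) {
      z <- z + cfg$trait_assoc_strength * as.vector(scale(tv))
    }
    z <- as.vector(scale(z))
    latents[mi, ] <- z
    rho <- cfg$module_cor
    for (g in members) {
      e <- rnorm(nrow(joint_si))
      log2ps[g, ] <- log2ps[g, ] +
        cfg$module_signal_sd * (sqrt(rho) * z + sqrt(1 - rho) * e)
    }
  }
  module_gene_idx <- which(module_assign != "unassigned")

  # planted responders, per species, disjoint from module genes
  responder_pool <- setdiff(seq_len(n_genes), module_gene_idx)
  responders <- list()
  fc_profiles <- list()
  for (sp in species) {
    si_sp <- sample_tables[[sp]]
    span <- sp_span(sp)
    idx <- sort(sample(responder_pool, cfg$n_responders))
    if (cfg$n_responders > 0) {
      first <- sample(post_tps, cfg$n_responders, replace = TRUE)
      highest <- vapply(first, function(f) {
        later <- post_tps[match(f, post_tps):length(post_tps)]
        if (length(later) == 1) later else sample(later, 1)
      }, character(1))
      effect <- runif(cfg$n_responders, cfg$responder_effect_range[1],
                      cfg$responder_effect_range[2])
      for (i in seq_len(cfg$n_responders)) {
        g <- idx[i]
        for (tp in post_tps) {
          if (match(tp, post_tps) < match(first[i], post_tps)) next
          fc <- if (tp == highest[i]) effect[i] else
            cfg$secondary_peak_factor * effect[i]
          cols <- span[si_sp$condition == "WD" & si_sp$timepoint == tp]
          log2ps[g, cols] <- log2ps[g, cols] + fc
        }
      }
      responders[[sp]] <- tibble::tibble(
        species = sp, gene_id = gene_ids[[sp]][idx],
        first_peak = first, highest_peak = highest, effect = effect)
      fc_profiles[[sp]] <- tidyr::expand_grid(i = seq_len(cfg$n_responders),
                                              timepoint = post_tps) %>%
        mutate(species = sp,
               gene_id = gene_ids[[sp]][idx[.data$i]],
               log2fc = purrr::map2_dbl(.data$i, .data$timepoint, function(i, tp) {
                 if (match(tp, post_tps) < match(first[i], post_tps)) return(0)
                 if (tp == highest[i]) effect[i] else
                   cfg$secondary_peak_factor * effect[i]
               })) %>%
        select("species", "gene_id", "timepoint", "log2fc")
    }
  }

  # replicate noise, back-transform, transcript split
  species_data <- list()
  for (sp in species) {
    span <- sp_span(sp)
    signal <- log2ps[, span, drop = FALSE]
    if (cfg$noise_sd > 0) {
      signal <- signal + matrix(rnorm(length(signal), sd = cfg$noise_sd),
                                nrow = nrow(signal))
    }
    gene_tpm <- pmax(2^signal - 1, 0)
    rownames(gene_tpm) <- gene_ids[[sp]]
    colnames(gene_tpm) <- sample_tables[[sp]]$sample_id

    n_tx <- sample(seq(cfg$transcripts_range[1], cfg$transcripts_range[2]),
                   n_genes, replace = TRUE)
    tx_gene <- rep(seq_len(n_genes), n_tx)
    weights <- unlist(lapply(n_tx, function(k) {
      w <- rgamma(k, shape = 2)
      w / sum(w)
    }))
    tx_ids <- unlist(lapply(seq_len(n_genes), function(g) {
      sprintf("%s.t%d", gene_ids[[sp]][g], seq_len(n_tx[g]))
    }))
    tx_tpm <- gene_tpm[tx_gene, , drop = FALSE] * weights
    rownames(tx_tpm) <- tx_ids
    tx2gene <- tibble::tibble(transcript_id = tx_ids,
                              gene_id = gene_ids[[sp]][tx_gene])
    species_data[[sp]] <- list(
      tpm = expr_from_matrix(tx_tpm,
                             normalise_sample_info(sample_tables[[sp]],
                                                   cfg$timepoints),
                             "tpm"),
      tx2gene = tx2gene,
      metadata = sample_tables[[sp]])
  }

  ortho <- tibble::as_tibble(setNames(
    lapply(species, function(sp) gene_ids[[sp]][seq_len(n_ortho)]), species))

  module_tbl <- bind_rows(lapply(species, function(sp) {
    tibble::tibble(species = sp, gene_id = gene_ids[[sp]],
                   ortho_index = seq_len(n_genes),
                   module = module_assign)
  }))

  structure(list(
    species_data = species_data,
    truth = list(ortho = ortho,
                 modules = module_tbl,
                 module_latents = latents,
                 responders = bind_rows(responders),
                 fc_profiles = bind_rows(fc_profiles),
                 baselines = base),
    config = cfg), class = "drought_sim")
}

#' @export
print.drought_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Synthetic drought course: %d species x %d genes, %s design, seed %d\n",
              length(cfg$species), cfg$n_genes,
              sprintf("%d conditions x %d timepoints x %d replicates", 2,
                      length(cfg$timepoints), cfg$n_replicates),
              cfg$seed))
  cat(sprintf("  planted: %d modules (%s genes), %d responders/species, %.0f%% orthologs\n",
              length(cfg$module_sizes),
              paste(cfg$module_sizes, collapse = "+"),
              cfg$n_responders, 100 * cfg$ortho_fraction))
  invisible(x)
}

#' Simulate fold-change profiles with planted timing classes
#'
#' Generates per-EMO, per-species log2 fold-change records at the post-onset
#' timepoints with a known timing class: for each EMO a segment class is
#' drawn (single-species specific, a synchronous or shifted species pair, or
#' all-species synchronous/shifted), induced species receive the planted
#' effect at their peaks (the highest peak carries the full effect, other
#' induced timepoints `secondary_factor` of it) and Gaussian noise is added
#' to every record.
#'
#' @param n_emo Number of EMOs to simulate.
#' @param species Species labels.
#' @param timepoints Post-onset timepoints.
#' @param effect_range Range of planted peak log2 fold changes.
#' @param noise_sd Noise standard deviation on log2 fold changes.
#' @param secondary_factor Fold-change multiplier at induced non-peak
#'   timepoints.
#' @param seed Integer seed.
#' @return A list with `fc` (tibble `emo_id`, `species`, `timepoint`,
#'   `log2fc`) and `truth` (tibble `emo_id`, `segment`, `effect`, plus
#'   per-species planted peaks in `peaks`).
#' @export
simulate_timing_profiles <- function(n_emo = 500,
                                     species = c("Ath", "Aly", "Esa"),
                                     timepoints = c("T5", "T11", "T14"),
                                     effect_range = c(1.5, 4),
                                     noise_sd = 0.1,
                                     secondary_factor = 0.9,
                                     seed = 1) {
  set.seed(seed)
  k <- length(species)
  stopifnot(k >= 2, length(timepoints) >= 2)
  subsets <- unlist(lapply(seq_len(k), function(size) {
    utils::combn(species, size, simplify = FALSE)
  }), recursive = FALSE)
  classes <- unlist(lapply(subsets, function(ss) {
    if (length(ss) == 1) list(list(induced = ss, timing = "specific"))
    else list(list(induced = ss, timing = "synchronous"),
              list(induced = ss, timing = "shifted"))
  }), recursive = FALSE)

  fc_rows <- vector("list", n_emo)
  truth_rows <- vector("list", n_emo)
  peak_rows <- vector("list", n_emo)
  for (i in seq_len(n_emo)) {
    cls <- classes[[sample.int(length(classes), 1)]]
    induced <- cls$induced
    m <- length(induced)
    firsts <- if (cls$timing == "shifted") {
      if (m <= length(timepoints)) {
        sample(timepoints, m, replace = FALSE)
      } else {
        repeat {
          draw <- sample(timepoints, m, replace = TRUE)
          if (length(unique(draw)) > 1) break
        }
        draw
      }
    } else {
      rep(sample(timepoints, 1), m)
    }
    names(firsts) <- induced
    effect <- setNames(runif(m, effect_range[1], effect_range[2]), induced)
    highest <- vapply(induced, function(sp) {
      later <- timepoints[match(firsts[sp], timepoints):length(timepoints)]
      if (length(later) == 1) later else sample(later, 1)
    }, character(1))
    emo <- sprintf("EMO%05d", i)
    grid <- tidyr::expand_grid(species = species, timepoint = timepoints)
    grid$log2fc <- purrr::map2_dbl(grid$species, grid$timepoint, function(sp, tp) {
      base <- 0
      if (sp %in% induced &&
          match(tp, timepoints) >= match(firsts[sp], timepoints)) {
        base <- if (tp == highest[sp]) effect[sp] else
          secondary_factor * effect[sp]
      }
      base
    })
    grid$log2fc <- grid$log2fc + rnorm(nrow(grid), sd = noise_sd)
    grid$emo_id <- emo
    fc_rows[[i]] <- grid
    truth_rows[[i]] <- tibble::tibble(
      emo_id = emo,
      segment = segment_code(species, induced, unname(firsts)),
      min_effect = min(effect))
    peak_rows[[i]] <- tibble::tibble(emo_id = emo, species = induced,
                                     first_peak = unname(firsts),
                                     highest_peak = unname(highest),
                                     effect = unname(effect))
  }
  fc <- bind_rows(fc_rows)
  fc$timepoint <- factor(fc$timepoint, levels = timepoints, ordered = TRUE)
  list(fc = fc[c("emo_id", "species", "timepoint", "log2fc")],
       truth = bind_rows(truth_rows),
       peaks = bind_rows(peak_rows))
}

#' Simulate pairwise protein-similarity searches for a planted orthology
#'
#' For every species pair, each planted ortholog pair receives mutual
#' top-scoring hits in both search directions; with probability
#' `decoy_rate` a strictly lower-scoring paralog decoy hit is added, and
#' with probability `missing_rate` the pair is dropped from that search
#' entirely. E-values decrease consistently with bitscore. The emitted
#' tables use the standard 12-column tabular layout.
#'
#' @param ortho A tibble with one column per species; each row is a planted
#'   ortholog tuple.
#' @param decoy_rate,missing_rate Per-pair probabilities (see above).
#' @param seed Integer seed.
#' @return A list with `hits` (named list of tibbles, one per search
#'   direction, named `"A_vs_B"`), `triples` (rows of `ortho` present in
#'   every pairwise search) and `n_dropped`.
#' @export
simulate_orthology <- function(ortho, decoy_rate = 0.2, missing_rate = 0,
                               seed = 1) {
  ortho <- tibble::as_tibble(ortho)
  species <- names(ortho)
  stopifnot(length(species) >= 2)
  check_number(decoy_rate, "decoy_rate", lower = 0, upper = 1)
  check_number(missing_rate, "missing_rate", lower = 0, upper = 1)
  set.seed(seed)
  n <- nrow(ortho)
  hits <- list()
  kept_all <- rep(TRUE, n)
  make_rows <- function(q, s, bitscore) {
    len <- sample(100:600, length(q), replace = TRUE)
    tibble::tibble(qseqid = q, sseqid = s,
                   pident = round(runif(length(q), 55, 95), 1),
                   length = len,
                   mismatch = round(len * runif(length(q), 0.05, 0.3)),
                   gapopen = sample(0:5, length(q), replace = TRUE),
                   qstart = 1, qend = len, sstart = 1, send = len,
                   evalue = 10^(-bitscore / 12),
                   bitscore = round(bitscore, 1))
  }
  pairs <- utils::combn(species, 2, simplify = FALSE)
  for (pr in pairs) {
    a <- ortho[[pr[1]]]
    b <- ortho[[pr[2]]]
    kept <- runif(n) >= missing_rate
    kept_all <- kept_all & kept
    ai <- a[kept]
    bi <- b[kept]
    s <- runif(sum(kept), 500, 1500)
    fwd <- make_rows(ai, bi, s)
    rev <- make_rows(bi, ai, s * runif(sum(kept), 0.95, 0.999))
    # paralog decoys: strictly below the true hit's bitscore
    add_decoys <- function(tbl, queries, subjects, scores) {
      take <- runif(length(queries)) < decoy_rate
      if (sum(take) == 0 || length(subjects) < 2) return(tbl)
      wrong <- vapply(which(take), function(i) {
        sample(subjects[-i], 1)
      }, character(1))
      bind_rows(tbl, make_rows(queries[take], wrong,
                               scores[take] * runif(sum(take), 0.4, 0.8)))
    }
    fwd <- add_decoys(fwd, ai, bi, s)
    rev <- add_decoys(rev, bi, ai, s)
    hits[[sprintf("%s_vs_%s", pr[1], pr[2])]] <- fwd
    hits[[sprintf("%s_vs_%s", pr[2], pr[1])]] <- rev
  }
  list(hits = hits, triples = ortho[kept_all, ],
       n_dropped = sum(!kept_all))
}

#' Write similarity hits in 12-column tabular format
#'
#' @param hits A hits tibble (as produced by [simulate_orthology()] or read
#'   by [read_blast_tab()]).
#' @param path Output path (no header, tab-separated).
#' @return `hits`, invisibly.
#' @export
write_blast_tab <- function(hits, path) {
  readr::write_tsv(hits, path, col_names = FALSE, progress = FALSE)
  invisible(hits)
}

#' Simulate rosette growth trajectories with planted divergence
#'
#' Per-plant daily projected rosette area follows a logistic growth curve
#' with multiplicative noise; in the water-deficit arm the growth rate is
#' scaled down by `wd_rate_factor` for every day at or after the species'
#' planted divergence day, so that the divergence day is the first day on
#' which WD areas fall below WW areas. Perimeter and convex-hull area are
#' derived from the area through per-plant shape factors, keeping stockiness
#' and compactness within (0, 1]. Survival after rewatering is drawn per
#' species.
#'
#' @param species Species labels.
#' @param params Growth settings; defaults from `simulation_config()$growth`
#'   (days 0-14, 27 plants x 3 replicates per arm, species-specific starting
#'   areas, divergence days and survival probabilities).
#' @param seed Integer seed.
#' @return A list with `series` (tibble: `plant_id`, `species`, `treatment`,
#'   `replicate`, `day`, `area`, `perimeter`, `hull_area`, `survived`) and
#'   `truth` (divergence days and survival probabilities).
#' @export
simulate_growth <- function(species = c("Ath", "Aly", "Esa"),
                            params = list(), seed = 1) {
  p <- utils::modifyList(default_growth_params(species), params)
  set.seed(seed)
  days <- p$days
  rows <- list()
  for (sp in species) {
    n_plants <- p$n_plants_per_replicate * p$n_replicates
    for (pl in seq_len(n_plants)) {
      # per-plant biology is drawn once and shared by the two watering arms
      # (counterfactual twins), so a noise-free run without divergence
      # yields identical trajectories in WW and WD
      a0 <- p$area0[[sp]] * exp(rnorm(1, sd = p$plant_sd))
      r_p <- p$growth_rate * exp(rnorm(1, sd = p$plant_sd / 2))
      st <- runif(1, p$stockiness_range[1], p$stockiness_range[2])
      cp <- runif(1, p$compactness_range[1], p$compactness_range[2])
      for (treatment in c("WW", "WD")) {
        area <- numeric(length(days))
        area[1] <- a0
        for (d in seq_along(days)[-1]) {
          rate <- r_p * (1 - area[d - 1] / p$capacity)
          if (treatment == "WD" && days[d] >= p$divergence_day[[sp]]) {
            rate <- rate * p$wd_rate_factor
          }
          area[d] <- area[d - 1] *
            exp(rate * (days[d] - days[d - 1]) + rnorm(1, sd = p$noise_sd))
        }
        st_day <- pmin(pmax(st * exp(rnorm(length(days), sd = p$noise_sd / 2)),
                            0.01), 1)
        cp_day <- pmin(pmax(cp * exp(rnorm(length(days), sd = p$noise_sd / 2)),
                            0.05), 1)
        survived <- if (treatment == "WD") {
          runif(1) < p$survival_prob[[sp]]
        } else {
          TRUE
        }
        rows[[length(rows) + 1]] <- tibble::tibble(
          plant_id = sprintf("%s_%s_p%03d", sp, treatment, pl),
          species = sp, treatment = treatment,
          replicate = ((pl - 1) %/% p$n_plants_per_replicate) + 1L,
          day = days, area = area,
          perimeter = sqrt(4 * pi * area / st_day),
          hull_area = area / cp_day,
          survived = survived)
      }
    }
  }
  list(series = bind_rows(rows),
       truth = list(divergence_day = p$divergence_day,
                    survival_prob = p$survival_prob))
}

#' Simulate a gene-to-term annotation table
#'
#' Assigns random terms to universe genes, optionally planting an enriched
#' term whose members preferentially come from a given gene set, and
#' optionally emitting a simple term tree (binary parent chain) for
#' propagation tests.
#'
#' @param universe Character vector of gene ids.
#' @param n_terms Number of background terms.
#' @param avg_terms_per_gene Mean number of terms per gene (Poisson).
#' @param enriched Optional list with `genes` (character vector) and
#'   `term_id`; the planted term annotates those genes with probability
#'   `hit_rate` and the rest at `background_rate`.
#' @param with_parents Also return a `parents` edge table.
#' @param seed Integer seed.
#' @return A list with `annotation` (gene_id, term_id) and optionally
#'   `parents`.
#' @export
simulate_annotation <- function(universe, n_terms = 25,
                                avg_terms_per_gene = 2, enriched = NULL,
                                with_parents = FALSE, seed = 1) {
  set.seed(seed)
  terms <- sprintf("TERM:%04d", seq_len(n_terms))
  n_per_gene <- pmin(stats::rpois(length(universe), avg_terms_per_gene),
                     n_terms)
  ann <- tibble::tibble(
    gene_id = rep(universe, n_per_gene),
    term_id = unlist(lapply(n_per_gene, function(k) sample(terms, k))))
  if (!is.null(enriched)) {
    hit_rate <- enriched$hit_rate %||% 0.8
    background_rate <- enriched$background_rate %||% 0.05
    in_set <- universe %in% enriched$genes
    p_hit <- ifelse(in_set, hit_rate, background_rate)
    hits <- universe[runif(length(universe)) < p_hit]
    ann <- bind_rows(ann, tibble::tibble(gene_id = hits,
                                         term_id = enriched$term_id))
  }
  ann <- distinct(ann)
  out <- list(annotation = ann)
  if (with_parents) {
    all_terms <- unique(ann$term_id)
    idx <- seq_along(all_terms)
    child <- all_terms[idx > 1]
    parent <- all_terms[(idx[idx > 1]) %/% 2]
    out$parents <- tibble::tibble(term_id = child, parent_id = parent)
  }
  out
}

#' Write a simulated study to disk in the pipeline's input formats
#'
#' Emits, per species, the transcript TPM table, the sample metadata table
#' and the transcript-to-gene map as TSV, exactly as the corresponding
#' readers expect them.
#'
#' @param sim A `drought_sim` from [simulate_expression()].
#' @param dir Output directory (created if needed).
#' @return A named list of written file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "drought_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (sp in names(sim$species_data)) {
    sd_sp <- sim$species_data[[sp]]
    expr_path <- file.path(dir, sprintf("%s_tpm.tsv", sp))
    meta_path <- file.path(dir, sprintf("%s_metadata.tsv", sp))
    map_path <- file.path(dir, sprintf("%s_tx2gene.tsv", sp))
    write_tpm_table(sd_sp$tpm, expr_path, meta_path)
    readr::write_tsv(sd_sp$tx2gene, map_path, progress = FALSE)
    paths[[sp]] <- c(expression = expr_path, metadata = meta_path,
                     tx2gene = map_path)
  }
  invisible(paths)
}
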