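#' Pipeline configuration
#'
#' Builds the configuration driving [run_pipeline()]: either a synthetic
#' study (the default; see [simulation_config()]) or file inputs, the stage
#' toggles, and every stage parameter. `validate_config()` checks a config
#' (or a YAML file containing one) and reports all violations at once.
#'
#' @param seed Integer master seed; stage-specific streams are derived from
#'   it.
#' @param out_dir Optional directory: when set, every intermediate table and
#'   the JSON report are written there.
#' @param simulation Named overrides for [simulation_config()] (ignored when
#'   `inputs` is given).
#' @param inputs Optional list of input paths: `species` (per species:
#'   `expression`, `metadata`, `tx2gene` TSVs), `hits` (per direction
#'   `"A_vs_B"`: tabular similarity files), optional `annotation` (two-column
#'   TSV) and `growth` (rosette series TSV). `NULL` means simulate.
#' @param stages Named logical toggles: `orthology`, `timing`, `overlap`,
#'   `modules`, `enrichment`, `phenotype`.
#' @param filter_threshold Expression filter on log2(TPM+1) (default 1).
#' @param pseudocount Pseudocount for logs and fold changes (default 1).
#' @param fc_up,fc_down Inclusive regulation thresholds (default +1/-1).
#' @param max_evalue E-value cutoff for similarity hits (default 1e-3).
#' @param beta,network_type,min_module_size,cut_height_fraction,merge_dissimilarity
#'   Co-expression network parameters (see [detect_modules()]).
#' @param n_perm Permutations for the overlap test (default 1000).
#' @param overlap_timepoint Timepoint whose commonly upregulated EMOs are
#'   tested (default `"T11"`).
#' @param fdr_level Module-trait significance threshold (default 0.05).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, out_dir = NULL, simulation = list(),
                            inputs = NULL,
                            stages = list(),
                            filter_threshold = 1, pseudocount = 1,
                            fc_up = 1, fc_down = -1, max_evalue = 1e-3,
                            beta = 16, network_type = "unsigned",
                            min_module_size = 30,
                            cut_height_fraction = 0.99,
                            merge_dissimilarity = 0.1,
                            n_perm = 1000, overlap_timepoint = "T11",
                            fdr_level = 0.05) {
  default_stages <- list(orthology = TRUE, timing = TRUE, overlap = TRUE,
                         modules = TRUE, enrichment = TRUE, phenotype = TRUE)
  cfg <- list(seed = as.integer(seed), out_dir = out_dir,
              simulation = simulation, inputs = inputs,
              stages = utils::modifyList(default_stages, stages),
              filter_threshold = filter_threshold, pseudocount = pseudocount,
              fc_up = fc_up, fc_down = fc_down, max_evalue = max_evalue,
              beta = beta, network_type = network_type,
              min_module_size = min_module_size,
              cut_height_fraction = cut_height_fraction,
              merge_dissimilarity = merge_dissimilarity,
              n_perm = as.integer(n_perm),
              overlap_timepoint = overlap_timepoint,
              fdr_level = fdr_level)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param x A `pipeline_config`, a plain list, or the path of a YAML file
#'   holding one.
#' @return `validate_config()` returns the validated `pipeline_config`, or
#'   aborts with every violation listed.
#' @export
validate_config <- function(x) {
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) abort(sprintf("Config file not found: %s", x))
    x <- yaml::read_yaml(x)
  }
  if (!inherits(x, "pipeline_config")) {
    known <- names(formals(pipeline_config))
    x <- do.call(pipeline_config, x[intersect(names(x), known)])
  }
  problems <- character()
  add <- function(field, reason) {
    problems <<- c(problems, sprintf("%s: %s", field, reason))
  }
  num_checks <- list(
    beta = c(.Machine$double.eps, Inf),
    filter_threshold = c(-Inf, Inf),
    pseudocount = c(0, Inf),
    max_evalue = c(0, Inf),
    cut_height_fraction = c(.Machine$double.eps, 1),
    merge_dissimilarity = c(0, 2),
    min_module_size = c(1, Inf),
    n_perm = c(1, Inf),
    fdr_level = c(0, 1))
  for (field in names(num_checks)) {
    v <- x[[field]]
    rng <- num_checks[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      add(field, "must be a single finite number")
    } else if (v < rng[1] || v > rng[2]) {
      add(field, sprintf("must lie in [%s, %s], got %s", rng[1], rng[2], v))
    }
  }
  if (!is.numeric(x$fc_up) || !is.numeric(x$fc_down) || x$fc_up <= x$fc_down) {
    add("fc_up/fc_down", "up-threshold must exceed down-threshold")
  }
  if (!x$network_type %in% c("unsigned", "signed")) {
    add("network_type", "must be 'unsigned' or 'signed'")
  }
  if (!is.null(x$inputs)) {
    for (sp in names(x$inputs$species %||% list())) {
      for (kind in c("expression", "metadata", "tx2gene")) {
        path <- x$inputs$species[[sp]][[kind]]
        if (is.null(path)) {
          add(sprintf("inputs.species.%s.%s", sp, kind), "missing path")
        } else if (!file.exists(path)) {
          add(sprintf("inputs.species.%s.%s", sp, kind),
              sprintf("file does not exist: %s", path))
        }
      }
    }
    for (nm in names(x$inputs$hits %||% list())) {
      if (!file.exists(x$inputs$hits[[nm]])) {
        add(sprintf("inputs.hits.%s", nm),
            sprintf("file does not exist: %s", x$inputs$hits[[nm]]))
      }
    }
  } else {
    sim_try <- tryCatch({
      do.call(simulation_config, c(list(seed = x$seed), x$simulation))
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(sim_try)) add("simulation", sim_try)
  }
  if (length(problems) > 0) {
    abort(paste0("Invalid pipeline config:\n",
                 paste0("- ", problems, collapse = "\n")))
  }
  x
}

write_stage_table <- function(tbl, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  readr::write_tsv(tibble::as_tibble(tbl), file.path(out_dir,
                                                     paste0(name, ".tsv")),
                   progress = FALSE)
}

#' Run the comparative drought-response pipeline end to end
#'
#' Executes the stages in dependency order: expression loading (or
#' simulation), transcript aggregation, log transform and expression filter;
#' reciprocal-best-hit orthology and the expressed-mutual-ortholog (EMO)
#' table; fold changes, regulation calls, overlap regions and peak-timing
#' segments; the permutation overlap test; co-expression module detection
#' and module-trait statistics; term enrichment of the largest module; and
#' rosette phenotyping metrics. Returns a machine-readable report whose
#' counts are internally consistent; a rerun with the same config and seed
#' reproduces the report bit-exactly.
#'
#' @param cfg A [pipeline_config()] (validated on entry).
#' @return A `pipeline_report` (nested list with a `print()` method). When
#'   `cfg$out_dir` is set, intermediates and `report.json` are written
#'   there.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  cfg <- validate_config(cfg)
  out_dir <- cfg$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  report <- list(provenance = list(
    package_version = as.character(utils::packageVersion("aridr")),
    seed = cfg$seed,
    # the hash identifies the analysis settings; the output location is not
    # part of the analysis
    config_hash = rlang::hash(unclass(cfg)[setdiff(names(cfg), "out_dir")])))

  # --- expression stage (always on) ---------------------------------------
  simulated <- is.null(cfg$inputs)
  if (simulated) {
    sim_cfg <- do.call(simulation_config,
                       c(list(seed = cfg$seed), cfg$simulation))
    sim <- simulate_expression(sim_cfg)
    species_raw <- lapply(sim$species_data, function(sd_sp) {
      list(tpm = sd_sp$tpm, tx2gene = sd_sp$tx2gene)
    })
  } else {
    sim <- NULL
    species_raw <- lapply(cfg$inputs$species, function(paths) {
      list(tpm = read_tpm_table(paths$expression, paths$metadata),
           tx2gene = readr::read_tsv(paths$tx2gene,
                                     col_types = readr::cols(.default = "c"),
                                     progress = FALSE))
    })
  }
  species <- names(species_raw)
  gene_tpm <- list()
  gene_log2 <- list()
  expressed <- list()
  expr_counts <- list()
  for (sp in species) {
    g <- aggregate_transcripts_to_genes(species_raw[[sp]]$tpm,
                                        species_raw[[sp]]$tx2gene)
    lg <- log2_transform(g, cfg$pseudocount)
    filt <- expression_filter(lg, cfg$filter_threshold, quiet = TRUE)
    gene_tpm[[sp]] <- g
    gene_log2[[sp]] <- lg
    expressed[[sp]] <- filt$feature_id
    expr_counts[[sp]] <- list(
      transcripts = nrow(species_raw[[sp]]$tpm),
      genes = nrow(g),
      expressed = length(expressed[[sp]]))
  }
  report$expression <- expr_counts

  # --- orthology -----------------------------------------------------------
  emo <- NULL
  if (isTRUE(cfg$stages$orthology) && length(species) >= 3) {
    if (simulated) {
      orth <- simulate_orthology(sim$truth$ortho,
                                 decoy_rate = sim_cfg$decoy_rate,
                                 missing_rate = sim_cfg$missing_rate,
                                 seed = cfg$seed + 1)
      hits <- orth$hits
    } else {
      hits <- lapply(cfg$inputs$hits, read_blast_tab,
                     max_evalue = cfg$max_evalue)
    }
    sp3 <- species[1:3]
    pair_of <- function(a, b) {
      reciprocal_best_hits(hits[[sprintf("%s_vs_%s", a, b)]],
                           hits[[sprintf("%s_vs_%s", b, a)]])
    }
    ab <- pair_of(sp3[1], sp3[2])
    ac <- pair_of(sp3[1], sp3[3])
    bc <- pair_of(sp3[2], sp3[3])
    emo <- build_emo_table(ab, ac, bc,
                           expressed = expressed[sp3], species = sp3)
    report$orthology <- list(
      pairs = list(ab = nrow(ab), ac = nrow(ac), bc = nrow(bc)),
      n_emo = nrow(emo),
      n_inconsistent_triangles = attr(emo, "n_inconsistent"))
    write_stage_table(emo, out_dir, "emo_table")
  } else {
    report$orthology <- "skipped"
  }

  # --- fold changes, regulation calls, timing ------------------------------
  emo_fc <- NULL
  up_sets <- NULL
  if (isTRUE(cfg$stages$timing)) {
    fc_all <- bind_rows(lapply(species, function(sp) {
      log2_fold_change(gene_tpm[[sp]], cfg$pseudocount)
    }))
    calls <- call_regulated(fc_all, cfg$fc_up, cfg$fc_down)
    counts <- de_counts(calls)
    specific <- bind_rows(lapply(species, function(sp) {
      drought_specific_genes(gene_log2[[sp]], cfg$filter_threshold)
    }))
    report$timing <- list(
      de_counts = as.data.frame(mutate(counts,
                                       timepoint = as.character(.data$timepoint),
                                       status = as.character(.data$status))),
      drought_specific = as.list(table(factor(specific$species,
                                              levels = species))))
    write_stage_table(calls, out_dir, "fold_changes")
    if (!is.null(emo) && nrow(emo) > 0) {
      emo_ids <- emo[[1]]  # first species' gene id names the triple
      emo_long <- tidyr::pivot_longer(
        mutate(emo, emo_id = emo_ids), -"emo_id",
        names_to = "species", values_to = "gene_id")
      emo_calls <- inner_join(emo_long, calls, by = c("species", "gene_id"))
      tps <- levels(calls$timepoint)
      post <- tps[-1]
      up_sets <- lapply(setNames(post, post), function(tp) {
        lapply(setNames(species[1:3], species[1:3]), function(sp) {
          emo_calls$emo_id[emo_calls$species == sp &
                             emo_calls$timepoint == tp &
                             emo_calls$status == "up"]
        })
      })
      venns <- lapply(up_sets, venn_overlaps)
      timing_tbl <- classify_peak_timing(
        filter(emo_calls, .data$timepoint != tps[1])[
          c("emo_id", "species", "timepoint", "log2fc")],
        up = cfg$fc_up, species_order = species[1:3])
      seg <- distinct(timing_tbl[c("emo_id", "segment")])
      report$timing$venn_up <- lapply(venns, as.data.frame)
      report$timing$segments <- as.list(table(seg$segment))
      write_stage_table(timing_tbl, out_dir, "peak_timing")
    }
  } else {
    report$timing <- "skipped"
  }

  # --- permutation overlap test -------------------------------------------
  if (isTRUE(cfg$stages$overlap) && !is.null(up_sets) &&
      cfg$overlap_timepoint %in% names(up_sets)) {
    sets <- up_sets[[cfg$overlap_timepoint]]
    observed <- length(Reduce(intersect, sets))
    perm <- permutation_overlap_test(
      background = emo[[1]],
      set_sizes = lengths(sets),
      observed = observed,
      n = cfg$n_perm, seed = cfg$seed + 2)
    report$overlap <- c(list(timepoint = cfg$overlap_timepoint),
                        as.list(glance(perm)))
  } else {
    report$overlap <- "skipped"
  }

  # --- co-expression modules ----------------------------------------------
  modules <- NULL
  if (isTRUE(cfg$stages$modules) && !is.null(emo) && nrow(emo) >= 2) {
    emo_ids <- emo[[1]]
    mats <- lapply(species[1:3], function(sp) {
      m <- expr_values(gene_log2[[sp]])[emo[[sp]], , drop = FALSE]
      rownames(m) <- emo_ids
      m
    })
    joint <- do.call(cbind, mats)
    joint_si <- bind_rows(lapply(species[1:3], function(sp) {
      sample_info(gene_log2[[sp]])
    }))
    modules <- detect_modules(joint, beta = cfg$beta,
                              network_type = cfg$network_type,
                              min_module_size = cfg$min_module_size,
                              cut_height_fraction = cfg$cut_height_fraction,
                              merge_dissimilarity = cfg$merge_dissimilarity)
    mt <- if (nrow(modules$eigengenes) > 0) {
      module_trait_correlation(modules, build_trait_matrix(joint_si),
                               fdr_level = cfg$fdr_level)
    } else {
      NULL
    }
    sizes <- table(modules$assignments$module)
    report$modules <- list(
      n_modules = sum(names(sizes) != "unassigned"),
      sizes = as.list(sizes[setdiff(names(sizes), "unassigned")]),
      n_unassigned = sum(modules$assignments$module == "unassigned"),
      n_significant_module_trait = if (is.null(mt)) 0 else
        sum(mt$significant, na.rm = TRUE))
    write_stage_table(modules$assignments, out_dir, "module_assignments")
    if (!is.null(mt)) write_stage_table(mt, out_dir, "module_trait")
  } else {
    report$modules <- "skipped"
  }

  # --- enrichment ----------------------------------------------------------
  if (isTRUE(cfg$stages$enrichment) && !is.null(modules) &&
      any(modules$assignments$module != "unassigned")) {
    universe <- modules$assignments$feature_id
    study <- modules$assignments$feature_id[
      modules$assignments$module == "M1"]
    if (simulated) {
      ann <- simulate_annotation(universe,
                                 enriched = list(genes = study,
                                                 term_id = "TERM:PLANTED"),
                                 seed = cfg$seed + 4)$annotation
    } else if (!is.null(cfg$inputs$annotation)) {
      ann <- read_annotation_table(cfg$inputs$annotation)
    } else {
      ann <- NULL
    }
    if (!is.null(ann)) {
      enr <- fisher_enrichment(study, universe, ann)
      report$enrichment <- list(
        study_module = "M1", n_study = length(study),
        n_terms_tested = nrow(enr),
        n_significant = sum(enr$fdr < cfg$fdr_level),
        top_term = if (nrow(enr) > 0) enr$term_id[1] else NA_character_)
      write_stage_table(enr, out_dir, "enrichment")
    } else {
      report$enrichment <- "skipped"
    }
  } else {
    report$enrichment <- "skipped"
  }

  # --- phenotyping ---------------------------------------------------------
  if (isTRUE(cfg$stages$phenotype)) {
    if (simulated) {
      growth <- simulate_growth(species, sim_cfg$growth, seed = cfg$seed + 3)
      series <- growth$series
    } else if (!is.null(cfg$inputs$growth)) {
      series <- readr::read_tsv(cfg$inputs$growth,
                                col_types = readr::cols(), progress = FALSE)
    } else {
      series <- NULL
    }
    if (!is.null(series)) {
      surv <- survival_rate(filter(series, .data$treatment == "WD",
                                   .data$day == max(.data$day)))
      onset <- lapply(setNames(unique(series$species),
                               unique(series$species)), function(sp) {
        sub <- filter(series, .data$species == sp)
        day <- first_growth_reduction_day(
          filter(sub, .data$treatment == "WW"),
          filter(sub, .data$treatment == "WD"))
        if (is.na(day)) NA else as.numeric(day)
      })
      shape <- series %>%
        group_by(.data$species, .data$treatment) %>%
        summarise(mean_stockiness = mean(stockiness(.data$area,
                                                    .data$perimeter)),
                  mean_compactness = mean(compactness(.data$area,
                                                      .data$hull_area)),
                  .groups = "drop")
      report$phenotype <- list(
        survival = as.data.frame(select(surv, -"treatment")),
        first_growth_reduction_day = onset,
        shape = as.data.frame(shape))
      write_stage_table(series, out_dir, "growth_series")
    } else {
      report$phenotype <- "skipped"
    }
  } else {
    report$phenotype <- "skipped"
  }

  class(report) <- "pipeline_report"
  if (!is.null(out_dir)) {
    jsonlite::write_json(unclass(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Drought-response pipeline report\n")
  cat(sprintf("  seed %d, config %s\n", x$provenance$seed,
              substr(x$provenance$config_hash, 1, 8)))
  for (sp in names(x$expression)) {
    e <- x$expression[[sp]]
    cat(sprintf("  %s: %d transcripts -> %d genes, %d expressed\n",
                sp, e$transcripts, e$genes, e$expressed))
  }
  if (!identical(x$orthology, "skipped")) {
    cat(sprintf("  EMO triples: %d (inconsistent triangles: %d)\n",
                x$orthology$n_emo, x$orthology$n_inconsistent_triangles))
  }
  if (!identical(x$overlap, "skipped")) {
    cat(sprintf("  overlap at %s: observed %d, %s\n", x$overlap$timepoint,
                x$overlap$observed_overlap, x$overlap$p_text))
  }
  if (!identical(x$modules, "skipped")) {
    cat(sprintf("  modules: %d (%d unassigned genes), %d significant module-trait pairs\n",
                x$modules$n_modules, x$modules$n_unassigned,
                x$modules$n_significant_module_trait))
  }
  if (!identical(x$phenotype, "skipped")) {
    surv <- x$phenotype$survival
    cat(sprintf("  WD survival: %s\n",
                paste(sprintf("%s %.0f%%", surv$species, surv$mean_pct),
                      collapse = ", ")))
  }
  invisible(x)
}
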