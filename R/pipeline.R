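## End-to-end orchestration: simulate -> scan -> trees -> date -> reconcile
## -> synteny -> metabolites -> report.

#' Default pipeline configuration (the study scenario)
#'
#' Eight single-copy species-tree genes of 2000 nt each under the JC69
#' strict clock on the default chronogram, calibrations at the Ranunculales
#' (110 +/- 5 MY) and Papaveraceae (77 +/- 4 MY) crowns, the
#' [study_event_plan()] gene-family history, 100 bootstrap replicates with
#' a 0.7 support threshold, a 5 kb pairing distance, 9-13 aa linker bounds,
#' 80% module coverage, a complete five-gene cluster in the
#' P. bracteatum / P. somniferum / P. setigerum clade, and 10x-LOD
#' metabolite calling against the bundled printed presence table.
#'
#' @return a named list of settings.
#' @export
default_config <- function() {
  list(
    n_species_genes = 8L,
    gene_length = 2000L,
    clock_rate = 1.396e-8,
    species_tree_method = "bionj",
    outgroup = "Aquilegia",
    calibrations = list(
      list(leaves = c("Aquilegia", "Pso"), age = 110, sd = 5),
      list(leaves = c("Eschscholzia", "Pso"), age = 77, sd = 4)
    ),
    module_clock_rate = 3.4e-9,
    module_bp = c(900L, 600L),
    bootstrap_n = 100L,
    min_support = 0.7,
    min_coverage = 0.8,
    linker_bounds = c(9L, 13L),
    pair_distance = 5000,
    rbh_min_norm_score = 0.9,
    cluster_species = c("Pbr", "Pso", "Pse"),
    cluster_max_span = 1.2e6,
    lod_multiplier = 10,
    metab_slope = 1000,
    metab_noise_sd = 5,
    metab_dilution_points = 20L,
    metab_detected_multiple = 50,
    metab_nd_multiple = 2
  )
}

#' Read a pipeline configuration from a flat YAML file
#'
#' Scalar or vector keys override the defaults of [default_config()];
#' unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return a config list.
#' @export
read_config <- function(path) {
  cfg <- default_config()
  user <- yaml::read_yaml(path)
  bad <- setdiff(names(user), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(user)] <- user
  cfg
}

species_code_map <- function() c(
  "Papaver setigerum" = "Pse", "Papaver somniferum" = "Pso",
  "Papaver rhoeas" = "Prh", "Papaver dubium" = "Pdu",
  "Papaver armeniacum" = "Par", "Papaver triniifolium" = "Ptr",
  "Papaver bracteatum" = "Pbr", "Papaver orientale" = "Por",
  "Papaver atlanticum" = "Pat", "Papaver californicum" = "Pca",
  "Papaver nudicaule" = "Pnu", "Papaver pavonium" = "Ppa")

# append annotation rows for cluster genes on a species' contig
add_cluster_annotations <- function(layouts, species,
                                    labels = c("SALSYN", "SALR", "SALAT",
                                               "THS"),
                                    gene_bp = 1500L, spacing = 20000L) {
  rows <- list()
  for (sp in species) {
    ctg <- paste0("ctg_", sp)
    pos <- if (any(layouts$contig == ctg))
      max(layouts$end[layouts$contig == ctg]) else 0L
    for (lab in labels) {
      start <- pos + spacing
      rows[[paste0(sp, "_", lab)]] <- data.frame(
        contig = ctg, start = start, end = start + gene_bp, strand = "+",
        gene_id = paste0(sp, "_", lab), label = lab, role = "other",
        stringsAsFactors = FALSE)
      pos <- start + gene_bp
    }
  }
  out <- rbind(layouts, do.call(rbind, rows))
  out[order(out$contig, out$start), ]
}

md5_of <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 3)
  close(con)
  unname(tools::md5sum(f))
}

#' Run the full inference pipeline on simulated data
#'
#' Simulates the study scenario with known ground truth and runs every
#' inference stage: (1) a concatenated multi-gene species alignment is
#' simulated on the chronogram, a JC69/NJ tree is built, rooted on the
#' outgroup and dated by strict-clock least squares with the configured
#' calibrations; (2) the gene family (pairing, segmental duplication,
#' fusion, losses, rearrangement) is simulated and every gene scanned for
#' the bi-modular fusion; (3) bootstrap NJ module gene trees are built and
#' the fusion-derived subgroup tested for monophyly; (4) the gene trees are
#' LCA-reconciled against the species tree, Dollo losses inferred from the
#' detected carriers, and the fusion origin bracketed on the estimated
#' chronogram; (5) gene-cluster presence is assessed per species layout and
#' the cluster formation bracketed; (6) dilution series are simulated per
#' compound and the presence matrix called at the LOD multiplier. Results
#' are merged into one event history plus a reproducibility manifest.
#'
#' @param config configuration list from [default_config()] or
#'   [read_config()].
#' @param seed integer seed governing every stage.
#' @param chron chronogram to simulate on (default [papaver_chronogram()]).
#' @param events gene-family event plan (default [study_event_plan()]).
#' @param out_dir optional directory for report files.
#' @return a `pipeline_report` list; see Details in the vignette.
#' @export
run_pipeline <- function(config = default_config(), seed = 1L,
                         chron = papaver_chronogram(),
                         events = study_event_plan(), out_dir = NULL) {
  clock <- clock_model(rate = config$clock_rate,
                       length = config$gene_length)

  ## stage 1: species chronogram estimation ------------------------------
  set.seed(seed)
  alns <- lapply(seq_len(config$n_species_genes), function(g)
    simulate_alignment(chron, clock))
  names(alns) <- paste0("cos", seq_along(alns))
  concat <- concatenate_alignments(alns)
  dmat <- jc69_distance_matrix(concat)
  sp_tree <- root_tree(nj_tree(dmat, method = config$species_tree_method),
                       config$outgroup)
  cals <- lapply(config$calibrations, function(cl)
    calibration(cl$leaves, cl$age, cl$sd))
  dated <- ls_date_distances(sp_tree, dmat,
                             n_sites = nchar(concat[[1]]), cals)

  ## stage 2: gene family + fusion scan ----------------------------------
  bundle <- simulate_gene_family(
    chron, events = events,
    clock = clock_model(rate = config$module_clock_rate),
    module_bp = config$module_bp, seed = seed + 1L)
  panel <- module_panel(bundle$panel$P450, bundle$panel$oxidoreductase)
  calls <- scan_layout(bundle$layouts, bundle$sequences, panel,
                       pair_distance = config$pair_distance,
                       min_coverage = config$min_coverage,
                       linker_bounds = config$linker_bounds)
  classes <- vapply(calls, `[[`, character(1), "class")
  fusion_ids <- names(calls)[classes %in%
                               c("full_fusion", "truncated_fusion")]
  carriers <- sort(unique(species_prefix(fusion_ids)))

  ## stage 3: module gene trees + monophyly ------------------------------
  ln_ids <- bundle$genes$gene_id[bundle$genes$subgroup == "Ln" &
                                   !bundle$genes$pseudo]
  monophyly <- list()
  gene_trees <- list()
  for (role in c("P450", "oxidoreductase")) {
    aln <- module_alignment(bundle, role)
    gt <- bootstrap_support(aln, n = config$bootstrap_n,
                            outgroup = intersect(ln_ids, names(aln)))
    gene_trees[[role]] <- gt
    monophyly[[role]] <- is_monophyletic(
      gt, intersect(fusion_ids, gt$tip.label),
      min_support = config$min_support)
  }
  mono_joint <- list(
    monophyletic = all(vapply(monophyly, `[[`, logical(1),
                              "monophyletic")),
    support = min(vapply(monophyly, `[[`, numeric(1), "support"),
                  na.rm = TRUE))

  ## stage 4: reconciliation, Dollo losses, fusion bracket ---------------
  recs <- lapply(gene_trees, lca_reconcile, species_tree = chron)
  subgroups <- mapply(extract_subgroups, gene_trees, recs,
                      MoreArgs = list(min_support = config$min_support),
                      SIMPLIFY = FALSE)
  est_chron <- dated$chronogram
  dollo <- dollo_losses(est_chron, carriers)
  loss_species <- unlist(dollo$loss_species)
  bracket <- bracket_fusion(est_chron, carriers, mono_joint)

  ## stage 5: synteny + cluster bracket ----------------------------------
  layouts2 <- add_cluster_annotations(bundle$layouts,
                                      config$cluster_species)
  cluster_by_sp <- lapply(setNames(nm = unique(bundle$genes$species)),
    function(sp) cluster_presence(
      layouts2[layouts2$contig == paste0("ctg_", sp), , drop = FALSE],
      max_span_bp = config$cluster_max_span))
  cluster_sp <- names(cluster_by_sp)[vapply(cluster_by_sp, `[[`,
                                            logical(1), "complete")]
  cluster_bracket <- if (length(cluster_sp) >= 2) {
    c(lower_my = mrca_age(est_chron, cluster_sp),
      upper_my = unname(bracket$lower_my))
  } else c(lower_my = NA_real_, upper_my = NA_real_)
  pairs_ord <- tryCatch(pair_order(bundle$layouts,
                                   config$pair_distance),
                        error = function(e) NULL)

  ## stage 6: metabolite presence ----------------------------------------
  set.seed(seed + 2L)
  printed <- papaver_presence()
  codes <- species_code_map()
  fits <- list()
  peaks <- list()
  dil <- 0.05 / 2^(seq_len(config$metab_dilution_points) - 1)
  for (cmp in colnames(printed)) {
    sim <- simulate_dilution_series(
      dil, slope = config$metab_slope, noise_sd = config$metab_noise_sd)
    fits[[cmp]] <- fit_lod(sim$calibration$conc, sim$calibration$response)
    true_lod <- sim$true_lod
    for (spn in rownames(printed)) {
      mult <- if (printed[spn, cmp] == "detected")
        config$metab_detected_multiple else config$metab_nd_multiple
      conc <- mult * true_lod
      peaks[[paste(spn, cmp)]] <- data.frame(
        species = codes[[spn]], compound = cmp,
        area = fits[[cmp]]$intercept + fits[[cmp]]$slope * conc,
        stringsAsFactors = FALSE)
    }
  }
  peaks <- do.call(rbind, peaks)
  presence <- call_presence(peaks, fits,
                            multiplier = config$lod_multiplier)
  class_counts <- summarize_matrix(presence)

  ## stage 7: event history + manifest -----------------------------------
  ages <- node_ages(est_chron)
  papaver_crown <- mrca_age(est_chron, c("Pnu", "Pso"))
  papaveraceae <- mrca_age(est_chron, c("Eschscholzia", "Pso"))
  hist_events <- list(
    list(kind = "pairing", branch = "Papaver stem",
         bracket_my = c(papaver_crown, papaveraceae),
         evidence = "linked module-gene pair in the outgroup lineage"),
    list(kind = "segmental_duplication", branch = "carrier-clade stem",
         bracket_my = c(bracket$lower_my %||% NA_real_,
                        bracket$upper_my %||% NA_real_),
         evidence = "sister unfused subgroup restricted to the carriers"),
    list(kind = "fusion", branch = "carrier-clade stem",
         bracket_my = c(bracket$lower_my %||% NA_real_,
                        bracket$upper_my %||% NA_real_),
         evidence = paste("monophyletic fused subgroups; carriers:",
                          paste(carriers, collapse = ","))),
    list(kind = "cluster_formation", branch = "cluster-clade stem",
         bracket_my = unname(cluster_bracket),
         evidence = paste("complete cluster in:",
                          paste(cluster_sp, collapse = ",")))
  )
  for (sp in loss_species)
    hist_events[[length(hist_events) + 1L]] <- list(
      kind = "loss", branch = sp, bracket_my = c(0, mrca_age_parent(
        est_chron, sp)),
      evidence = "carrier clade member without the fusion gene")
  if (!is.null(pairs_ord)) {
    flips <- pairs_ord[pairs_ord$order == "COR-first", , drop = FALSE]
    for (i in seq_len(nrow(flips)))
      hist_events[[length(hist_events) + 1L]] <- list(
        kind = "rearrangement", branch = species_prefix(flips$gene_p450[i]),
        bracket_my = c(0, mrca_age_parent(
          est_chron, species_prefix(flips$gene_p450[i]))),
        evidence = "pair order switched relative to the other species")
  }
  history <- assemble_event_history(hist_events)

  report <- list(
    seed = seed, config = config,
    rate = dated$rate,
    chronogram = est_chron,
    node_ages = list(papaver_crown_my = papaver_crown,
                     carrier_crown_my = bracket$lower_my %||% NA_real_,
                     papaveraceae_crown_my = papaveraceae),
    fusion_calls = classes,
    carriers = carriers,
    monophyly = monophyly,
    subgroups = subgroups,
    dollo = dollo,
    loss_species = sort(loss_species),
    fusion_bracket = bracket,
    cluster_bracket = cluster_bracket,
    cluster_species = cluster_sp,
    pair_orders = pairs_ord,
    presence = presence,
    class_counts = class_counts,
    event_history = history,
    truth = list(events = bundle$events, genes = bundle$genes)
  )
  report$manifest <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("fusionclock")),
    config_md5 = md5_of(config),
    stage_md5 = list(
      chronogram = md5_of(ape::write.tree(est_chron)),
      fusion_calls = md5_of(classes),
      bracket = md5_of(bracket),
      presence = md5_of(presence),
      history = md5_of(history)))
  class(report) <- "pipeline_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# age of the parent node above a tip or internal node
mrca_age_parent <- function(chron, tip) {
  v <- match(tip, chron$tip.label)
  p <- chron$edge[match(v, chron$edge[, 2]), 1]
  node_ages(chron)[p]
}

#' Write a pipeline report to disk
#'
#' JSON for the scalar results and event history, Newick for the estimated
#' chronogram, CSV for the presence matrix. Rerunning the pipeline with the
#' same config and seed rewrites byte-identical files.
#'
#' @param report a `pipeline_report`.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ape::write.tree(report$chronogram,
                  file = file.path(dir, "chronogram_estimate.nwk"))
  write.csv(as.data.frame(unclass(report$presence)),
            file.path(dir, "presence_matrix.csv"))
  keep <- c("seed", "rate", "node_ages", "fusion_calls", "carriers",
            "loss_species", "fusion_bracket", "cluster_bracket",
            "cluster_species", "class_counts", "manifest")
  jsonlite::write_json(report[keep], file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(report$event_history,
                     file.path(dir, "event_history.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("fusion-dating pipeline report (seed ", x$seed, ")\n", sep = "")
  cat("  fitted clock rate: ", format(x$rate, digits = 4),
      " subs/site/MY\n", sep = "")
  if (isTRUE(x$fusion_bracket$refused)) {
    cat("  fusion bracket refused: ", x$fusion_bracket$reason, "\n",
        sep = "")
  } else {
    cat(sprintf("  fusion origin bracket: [%.1f, %.1f] MY\n",
                x$fusion_bracket$lower_my, x$fusion_bracket$upper_my))
  }
  cat(sprintf("  cluster formation bracket: [%.1f, %.1f] MY\n",
              x$cluster_bracket[["lower_my"]],
              x$cluster_bracket[["upper_my"]]))
  cat("  carriers: ", paste(x$carriers, collapse = ", "), "\n", sep = "")
  cat("  losses: ", paste(x$loss_species, collapse = ", "), "\n", sep = "")
  cat("  class counts: ",
      paste(names(x$class_counts), x$class_counts, sep = "=",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
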