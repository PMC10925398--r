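# Declarative configuration and the deterministic stage pipeline. Each
# stage reads its inputs from and writes its outputs to a single run
# directory, so stages can be run one at a time (the CLI subcommands) or
# chained end to end with run_pipeline(). All thresholds live in the
# config; all randomness flows from one integer seed through fixed
# per-stage offsets.

#' Default pipeline configuration
#'
#' The simulate block encodes the emulated study design: a 3-batch
#' 16-channel discovery set and a 5-batch 18-channel replication set with
#' one GIS channel per batch, 2000 proteins with planted +-1 log2 AD
#' effects on 10%, and a 44-module reference brain network. Threshold
#' keys: 0.5 missingness, kME 0.30, tTau/Abeta ratio 0.226, MoCA cutoffs
#' 24/26, enrichment Z 1.96 with minimum 5 genes.
#'
#' @return nested configuration list
#' @export
default_config <- function() {
  list(
    simulate = list(
      n_sets = 2L, batches_per_set = c(3L, 5L),
      channels_per_batch = c(16L, 18L),
      n_proteins = 2000L, n_effect_proteins = 200L, delta_log2 = 1,
      sigma_batch = 0.5, sigma_channel = 0.1, sigma_noise = 0.25,
      missing_steepness = 4, missing_rate = 0.15,
      brain = list(n_modules = 44L, proteins_per_module = 25L,
                   n_samples = 100L, kme_target = 0.6, n_grey = 200L)),
    preprocess = list(
      max_missing_frac = 0.5,
      tampor = list(denominator = "gis", max_iter = 250L, tol = 1e-8),
      regress = list(covariates = c("batch_label", "age", "sex"),
                     protect = "diagnosis", n_boot = 100L)),
    differential = list(alpha = 0.05, cluster_q_max = 5e-4),
    meta = list(ratio_thresh = 0.226, moca_ad_max = 24, moca_ctl_min = 26),
    traits = list(min_significant = 3L, alpha = 0.05),
    netmap = list(kme_min = 0.30),
    enrich = list(min_genes = 5L, z_min = 1.96, q_max = 0.05))
}

#' Load a pipeline configuration
#'
#' Reads a YAML file and merges it over the defaults; `NULL` returns the
#' defaults unchanged.
#'
#' @param path YAML config path, a config list, or `NULL`
#' @return configuration list
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- if (is.list(path)) path else yaml::read_yaml(path)
  merge_lists(cfg, user)
}

merge_lists <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_lists(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- format_num(out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", check.names = FALSE,
                    na.strings = c("", "NA"), stringsAsFactors = FALSE)
}

write_list <- function(x, path) { writeLines(x, path); invisible(path) }

#' Run the full pipeline, or selected stages, into a run directory
#'
#' Stages: `simulate`, `preprocess`, `diff`, `meta`, `traits`, `netmap`,
#' `enrich`. `stages = "all"` chains them in order. Outputs are plain TSV
#' tables plus a JSON run manifest; repeated runs with the same seed and
#' config produce byte-identical outputs.
#'
#' @param config config list, YAML path, or `NULL` for defaults
#' @param seed master integer seed
#' @param out_dir run directory (created if absent)
#' @param stages character vector of stages or `"all"`
#' @return invisibly, the manifest list
#' @export
run_pipeline <- function(config = NULL, seed, out_dir, stages = "all") {
  if (missing(seed) || is.null(seed)) stopf("seed is required")
  cfg <- load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  all_stages <- c("simulate", "preprocess", "diff", "meta", "traits",
                  "netmap", "enrich")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  counts <- list()
  for (st in all_stages) {
    if (!st %in% stages) next
    hep_log("pipeline", "running stage ", st)
    counts[[st]] <- switch(st,
      simulate = stage_simulate(cfg, seed, out_dir),
      preprocess = stage_preprocess(cfg, seed, out_dir),
      diff = stage_diff(cfg, out_dir),
      meta = stage_meta(cfg, out_dir),
      traits = stage_traits(cfg, out_dir),
      netmap = stage_netmap(cfg, out_dir),
      enrich = stage_enrich(cfg, out_dir))
  }
  manifest <- list(seed = seed, stages = stages, config = cfg,
                   stage_counts = counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

stage_simulate <- function(cfg, seed, out_dir) {
  sc <- cfg$simulate
  sim <- simulate_tmt_plasma(
    n_sets = sc$n_sets, batches_per_set = unlist(sc$batches_per_set),
    channels_per_batch = unlist(sc$channels_per_batch),
    n_proteins = sc$n_proteins, n_effect_proteins = sc$n_effect_proteins,
    delta_log2 = sc$delta_log2, sigma_batch = sc$sigma_batch,
    sigma_channel = sc$sigma_channel, sigma_noise = sc$sigma_noise,
    missing_steepness = sc$missing_steepness, missing_rate = sc$missing_rate,
    seed = seed)
  write_abundance_matrix(sim$abundance, file.path(out_dir, "plasma_abundance.tsv"))
  write_sample_sheet(sim$sheet, file.path(out_dir, "sample_sheet.tsv"))
  write_trait_table(sim$traits, file.path(out_dir, "traits.tsv"))
  write_tsv(data.frame(protein_id = names(sim$truth$effect_sizes),
                       delta_log2 = unname(sim$truth$effect_sizes),
                       stringsAsFactors = FALSE),
            file.path(out_dir, "truth_effects.tsv"))

  # reference brain network over the same protein pool; the matrisome-like
  # module is seeded with planted up-regulated plasma proteins
  bc <- sc$brain
  set.seed(stage_seed(seed, 71L))
  ids <- names(sim$truth$effect_sizes)
  up_ids <- ids[sim$truth$effect_sizes > 0]
  n_members <- bc$n_modules * bc$proteins_per_module
  matrisome_ids <- up_ids[seq_len(min(bc$proteins_per_module, length(up_ids)))]
  pool <- setdiff(ids, matrisome_ids)
  other <- sample(pool, n_members - length(matrisome_ids) + bc$n_grey)
  module_ids <- sprintf("M%d", seq_len(bc$n_modules))
  matrisome_module <- if (bc$n_modules >= 42L) "M42" else module_ids[[bc$n_modules]]
  ordered <- character(0)
  oi <- 1L
  for (m in module_ids) {
    if (m == matrisome_module) {
      take <- matrisome_ids
      extra <- bc$proteins_per_module - length(take)
      if (extra > 0) { take <- c(take, other[oi:(oi + extra - 1L)]); oi <- oi + extra }
    } else {
      take <- other[oi:(oi + bc$proteins_per_module - 1L)]
      oi <- oi + bc$proteins_per_module
    }
    ordered <- c(ordered, take)
  }
  grey_ids <- other[oi:(oi + bc$n_grey - 1L)]
  brain <- simulate_reference_brain(
    n_modules = bc$n_modules, proteins_per_module = bc$proteins_per_module,
    n_samples = bc$n_samples, kme_target = bc$kme_target, n_grey = bc$n_grey,
    seed = stage_seed(seed, 72L), protein_ids = c(ordered, grey_ids),
    matrisome_module = matrisome_module)
  write_abundance_matrix(brain$abundance, file.path(out_dir, "brain_abundance.tsv"))
  write_network_reference(brain$ref, file.path(out_dir, "brain_membership.tsv"),
                          file.path(out_dir, "brain_eigenproteins.tsv"))
  write_tsv(brain$traits, file.path(out_dir, "brain_traits.tsv"))

  markers <- simulate_celltype_markers(brain$ref, seed = stage_seed(seed, 73L))
  write_gmt(markers, file.path(out_dir, "celltype_markers.gmt"))
  gmt <- simulate_gmt(gene_symbols(ids), n_random = 20L,
                      planted = list(MATRISOME_LIKE = gene_symbols(matrisome_ids)),
                      seed = stage_seed(seed, 74L))
  write_gmt(gmt, file.path(out_dir, "gene_sets.gmt"))
  list(n_proteins = nrow(sim$abundance), n_samples = ncol(sim$abundance),
       n_brain_proteins = nrow(brain$abundance))
}

stage_preprocess <- function(cfg, seed, out_dir) {
  pc <- cfg$preprocess
  M <- read_abundance_matrix(file.path(out_dir, "plasma_abundance.tsv"), "raw")
  sheet <- read_sample_sheet(file.path(out_dir, "sample_sheet.tsv"))
  counts <- list()
  for (s in unique(sheet$set_label)) {
    cols <- sheet$sample_id[sheet$set_label == s]
    Ms <- abundance_matrix(M[, cols, drop = FALSE], "raw")
    Ms <- Ms[rowSums(!is.na(Ms)) > 0L, , drop = FALSE]
    Ms <- abundance_matrix(Ms, "raw")
    norm <- channel_sum_normalize(Ms)
    filt <- filter_missingness(norm, pc$max_missing_frac)
    corr <- tampor(filt, sheet, denominator = pc$tampor$denominator,
                   max_iter = pc$tampor$max_iter, tol = pc$tampor$tol)
    covs <- intersect(unlist(pc$regress$covariates), colnames(sheet))
    # drop covariates that are constant within this set
    sub_sheet <- sheet[sheet$set_label == s, , drop = FALSE]
    covs <- covs[vapply(covs, function(v) length(unique(sub_sheet[[v]])) > 1L, TRUE)]
    corr <- bootstrap_covariate_regress(
      corr, sheet, covariates = covs, protect = pc$regress$protect,
      n_boot = pc$regress$n_boot, seed = stage_seed(seed, 81L))
    write_abundance_matrix(corr, file.path(out_dir, sprintf("corrected_%s.tsv", s)))
    counts[[s]] <- list(n_input = nrow(Ms), n_filtered = nrow(filt),
                        n_samples = ncol(Ms))
  }
  write_tsv(data.frame(set_label = names(counts),
                       n_input = vapply(counts, `[[`, 0, "n_input"),
                       n_filtered = vapply(counts, `[[`, 0, "n_filtered"),
                       n_samples = vapply(counts, `[[`, 0, "n_samples"),
                       stringsAsFactors = FALSE),
            file.path(out_dir, "qc_counts.tsv"))
  counts
}

read_corrected <- function(out_dir, set_label) {
  read_abundance_matrix(file.path(out_dir, sprintf("corrected_%s.tsv", set_label)),
                        "log2")
}

diagnosis_groups <- function(sheet, cols) {
  sub <- sheet[match(cols, sheet$sample_id), , drop = FALSE]
  keep <- !sub$is_gis & sub$diagnosis %in% c("Control", "AD")
  stats::setNames(sub$diagnosis[keep], sub$sample_id[keep])
}

stage_diff <- function(cfg, out_dir) {
  sheet <- read_sample_sheet(file.path(out_dir, "sample_sheet.tsv"))
  counts <- list()
  for (s in unique(sheet$set_label)) {
    M <- read_corrected(out_dir, s)
    groups <- diagnosis_groups(sheet, colnames(M))
    tab <- student_ttest_table(M, groups, alpha = cfg$differential$alpha)
    write_tsv(tab, file.path(out_dir, sprintf("diff_%s.tsv", s)))
    lists <- threshold_filter(tab, p_max = cfg$differential$alpha)
    write_list(lists$up, file.path(out_dir, sprintf("diff_%s_up.txt", s)))
    write_list(lists$down, file.path(out_dir, sprintf("diff_%s_down.txt", s)))
    # supervised clustering on the highly significant, completely observed
    top <- tab$protein_id[!is.na(tab$q_value) &
                            tab$q_value < cfg$differential$cluster_q_max]
    sub <- M[intersect(top, rownames(M)), names(groups), drop = FALSE]
    complete <- rownames(sub)[rowSums(is.na(sub)) == 0L]
    n_clustered <- 0L
    if (length(complete) >= 2L) {
      cl <- supervised_clustering(abundance_matrix(
        M[complete, names(groups), drop = FALSE], "log2"), complete)
      write_tsv(data.frame(sample_id = cl$order,
                           position = seq_along(cl$order),
                           stringsAsFactors = FALSE),
                file.path(out_dir, sprintf("cluster_%s_order.tsv", s)))
      write_tsv(data.frame(merge = seq_along(cl$heights), height = cl$heights),
                file.path(out_dir, sprintf("cluster_%s_heights.tsv", s)))
      n_clustered <- length(complete)
    }
    counts[[s]] <- list(n_tested = sum(!is.na(tab$p_value)),
                        n_up = length(lists$up), n_down = length(lists$down),
                        n_clustered = n_clustered)
  }
  counts
}

stage_meta <- function(cfg, out_dir) {
  sheet <- read_sample_sheet(file.path(out_dir, "sample_sheet.tsv"))
  traits <- read_trait_table(file.path(out_dir, "traits.tsv"))
  mc <- cfg$meta
  filtered <- sample_inclusion_filter(sheet, traits,
                                      ratio_thresh = mc$ratio_thresh,
                                      moca_ad_max = mc$moca_ad_max,
                                      moca_ctl_min = mc$moca_ctl_min)
  write_sample_sheet(filtered, file.path(out_dir, "inclusion_sheet.tsv"))
  sets <- unique(filtered$set_label)
  tabs <- list()
  for (s in sets) {
    M <- read_corrected(out_dir, s)
    cols <- intersect(colnames(M), filtered$sample_id)
    groups <- diagnosis_groups(filtered, cols)
    tabs[[s]] <- student_ttest_table(
      abundance_matrix(M[, cols, drop = FALSE], "log2"), groups,
      alpha = cfg$differential$alpha)
    write_tsv(tabs[[s]], file.path(out_dir, sprintf("diff_meta_%s.tsv", s)))
  }
  meta <- if (length(tabs) >= 2L) meta_table(tabs[[1L]], tabs[[2L]]) else
    data.frame(protein_id = tabs[[1L]]$protein_id,
               mean_log2fc = tabs[[1L]]$log2fc, meta_p = tabs[[1L]]$p_value,
               n_sets = 1L, stringsAsFactors = FALSE)
  write_tsv(meta, file.path(out_dir, "meta.tsv"))
  sig <- !is.na(meta$meta_p) & meta$meta_p < cfg$differential$alpha
  up <- meta$protein_id[sig & meta$mean_log2fc > 0]
  down <- meta$protein_id[sig & meta$mean_log2fc < 0]
  write_list(up, file.path(out_dir, "meta_up.txt"))
  write_list(down, file.path(out_dir, "meta_down.txt"))
  list(n_proteins = nrow(meta), n_up = length(up), n_down = length(down),
       n_samples_retained = sum(!filtered$is_gis))
}

stage_traits <- function(cfg, out_dir) {
  sheet <- read_sample_sheet(file.path(out_dir, "inclusion_sheet.tsv"))
  traits <- read_trait_table(file.path(out_dir, "traits.tsv"))
  sets <- unique(sheet$set_label)
  mats <- lapply(sets, function(s) {
    M <- read_corrected(out_dir, s)
    cols <- intersect(colnames(M), sheet$sample_id[!sheet$is_gis])
    M[, cols, drop = FALSE]
  })
  ids <- Reduce(union, lapply(mats, rownames))
  combined <- do.call(cbind, lapply(mats, function(m) {
    out <- matrix(NA_real_, length(ids), ncol(m), dimnames = list(ids, colnames(m)))
    out[rownames(m), ] <- m
    out
  }))
  ok <- rowSums(!is.na(combined)) >= 3L &
    apply(combined, 1L, stats::sd, na.rm = TRUE) > 0
  Z <- zscore_rows(abundance_matrix(combined[ok, , drop = FALSE], "log2"))
  write_abundance_matrix(Z, file.path(out_dir, "zscores.tsv"))
  C <- trait_correlation_table(Z, traits)
  tab <- data.frame(protein_id = rownames(Z), stringsAsFactors = FALSE)
  for (tr in colnames(C$r)) {
    tab[[paste0(tr, "_r")]] <- C$r[, tr]
    tab[[paste0(tr, "_p")]] <- C$p[, tr]
    tab[[paste0(tr, "_n")]] <- C$n[, tr]
  }
  write_tsv(tab, file.path(out_dir, "trait_correlations.tsv"))
  multi <- select_multitrait_proteins(C, cfg$traits$min_significant,
                                      cfg$traits$alpha)
  write_list(multi, file.path(out_dir, "multitrait_proteins.txt"))
  list(n_zscored = nrow(Z), n_multitrait = length(multi))
}

stage_netmap <- function(cfg, out_dir) {
  ref <- read_network_reference(file.path(out_dir, "brain_membership.tsv"),
                                file.path(out_dir, "brain_eigenproteins.tsv"))
  brain <- read_abundance_matrix(file.path(out_dir, "brain_abundance.tsv"), "log2")
  brain_traits <- read_tsv(file.path(out_dir, "brain_traits.tsv"))
  assign <- assign_to_modules(brain, ref, kme_min = cfg$netmap$kme_min,
                              mode = "reference")
  write_tsv(assign, file.path(out_dir, "module_assignment.tsv"))
  mt <- module_trait_bicor(ref$eigenproteins, brain_traits)
  mt_tab <- data.frame(module_id = rownames(mt$r), stringsAsFactors = FALSE)
  for (tr in colnames(mt$r)) {
    mt_tab[[paste0(tr, "_bicor")]] <- mt$r[, tr]
    mt_tab[[paste0(tr, "_p")]] <- mt$p[, tr]
  }
  write_tsv(mt_tab, file.path(out_dir, "module_trait_bicor.tsv"))

  up <- readLines(file.path(out_dir, "meta_up.txt"))
  down <- readLines(file.path(out_dir, "meta_down.txt"))
  background <- names(ref$membership)
  fet <- module_overlap_fet(intersect(up, background),
                            intersect(down, background), ref, background)
  write_tsv(fet, file.path(out_dir, "module_overlap_fet.tsv"))

  markers <- read_gmt(file.path(out_dir, "celltype_markers.gmt"))
  ct <- celltype_fet(ref, markers, background)
  write_tsv(ct, file.path(out_dir, "celltype_fet.tsv"))
  list(n_assigned = sum(assign$assigned_module != "grey"),
       n_grey = sum(assign$assigned_module == "grey"),
       n_sig_module_overlaps = sum(fet$q_bh < 0.05, na.rm = TRUE))
}

stage_enrich <- function(cfg, out_dir) {
  gmt <- read_gmt(file.path(out_dir, "gene_sets.gmt"))
  meta <- read_tsv(file.path(out_dir, "meta.tsv"))
  background <- gene_symbols(meta$protein_id)
  ec <- cfg$enrich
  counts <- list()
  for (dir in c("up", "down")) {
    fg <- gene_symbols(readLines(file.path(out_dir, sprintf("meta_%s.txt", dir))))
    if (!length(fg)) { counts[[dir]] <- 0L; next }
    tab <- go_fet(fg, background, gmt, min_genes = ec$min_genes,
                  z_min = ec$z_min, q_max = ec$q_max)
    write_tsv(tab, file.path(out_dir, sprintf("go_enrichment_%s.tsv", dir)))
    counts[[dir]] <- sum(tab$pass)
  }
  counts
}
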