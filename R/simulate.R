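# Synthetic-data generators with known ground truth.
#
# The TMT generator emulates the study design the pipeline targets: two
# independent sample sets (a 3-batch discovery set and a 5-batch
# replication set), 16-18 channels per batch with one pooled global
# internal standard (GIS) channel reserved per batch, multiplicative batch
# and channel effects, abundance-dependent (left-censored) missingness,
# planted AD log2 effects on a subset of proteins, and biomarker traits
# driven by a latent disease severity.

make_protein_ids <- function(n, prefix = "P", sym_prefix = "GENE") {
  sprintf("%s%05d|%s%05d", prefix, seq_len(n), sym_prefix, seq_len(n))
}

#' Simulate a multi-batch TMT plasma study with known truth
#'
#' Raw abundance is `2^(base_i + delta_i*I(AD) + gamma_{b,i} + lambda_j +
#' eps)` with `eps ~ N(0, sigma_noise)`. One channel per batch is the GIS:
#' the noiseless per-batch realization of a fixed virtual pool (batch and
#' channel effects apply, but no diagnosis effect and no measurement
#' noise), which makes internal-standard-anchored batch correction exactly
#' testable. Planted effects are `+delta_log2` for half of the effect
#' proteins and `-delta_log2` for the other half, mirroring the up- and
#' down-regulated halves of a disease contrast. Missingness probability is
#' a logistic function of the within-sample abundance rank: steepness 0
#' gives missing-completely-at-random at rate `missing_rate`.
#'
#' Traits are built from a latent severity (standard normal, shifted +1 SD
#' in AD): MoCA decreases with severity (clamped to 0..30), CSF
#' amyloid-beta 1-42 decreases, CSF tTau / pTau181 and plasma pTau181
#' increase, and the tTau/Abeta ratio is computed from its components.
#'
#' @param n_sets number of independent sample sets
#' @param batches_per_set batches in each set (scalar or length `n_sets`)
#' @param channels_per_batch TMT channels per batch including the GIS
#'   channel (scalar or length `n_sets`); must be >= 3
#' @param n_proteins number of proteins
#' @param n_effect_proteins number of proteins with a planted AD effect
#' @param delta_log2 magnitude of the planted log2 AD-Control difference
#' @param sigma_batch SD of per-(batch, protein) log2 offsets (centered to
#'   zero mean per protein across batches)
#' @param sigma_channel SD of per-sample log2 loadings
#' @param sigma_noise SD of residual log2 measurement noise
#' @param missing_steepness steepness of the logistic abundance-rank
#'   missingness model (0 = missing completely at random)
#' @param missing_rate overall missingness rate at the median abundance
#'   rank (0 disables missingness)
#' @param seed integer seed (required)
#' @param protein_ids optional explicit protein id vector
#' @return list with `abundance` (raw scale), `sheet`, `traits`, `truth`
#'   (effect sizes, batch effects, channel loadings, severity)
#' @export
simulate_tmt_plasma <- function(n_sets = 2L,
                                batches_per_set = c(3L, 5L),
                                channels_per_batch = c(16L, 18L),
                                n_proteins = 2000L,
                                n_effect_proteins = 200L,
                                delta_log2 = 1,
                                sigma_batch = 0.5,
                                sigma_channel = 0.1,
                                sigma_noise = 0.25,
                                missing_steepness = 4,
                                missing_rate = 0.15,
                                seed,
                                protein_ids = NULL) {
  if (missing(seed) || is.null(seed)) stopf("seed is required")
  if (any(c(sigma_batch, sigma_channel, sigma_noise) < 0))
    stopf("sigma parameters must be non-negative")
  if (n_effect_proteins > n_proteins)
    stopf("n_effect_proteins must be <= n_proteins")
  batches_per_set <- rep_len(as.integer(batches_per_set), n_sets)
  channels_per_batch <- rep_len(as.integer(channels_per_batch), n_sets)
  if (any(channels_per_batch < 3L)) stopf("channels_per_batch must be >= 3")
  set.seed(stage_seed(seed, 11L))

  ids <- protein_ids %||% make_protein_ids(n_proteins)
  stopifnot(length(ids) == n_proteins)
  base <- stats::rnorm(n_proteins, mean = 20, sd = 2)
  names(base) <- ids

  delta <- stats::setNames(numeric(n_proteins), ids)
  if (n_effect_proteins > 0L) {
    eff <- sample(ids, n_effect_proteins)
    sign <- rep(c(1, -1), length.out = n_effect_proteins)
    delta[eff] <- sign * delta_log2
  }

  sheet <- list(); cols <- list(); lambda_all <- c(); sev_all <- c()
  gamma_list <- list()
  for (s in seq_len(n_sets)) {
    for (b in seq_len(batches_per_set[[s]])) {
      batch_label <- sprintf("Set%d.b%d", s, b)
      nch <- channels_per_batch[[s]]
      sample_ids <- sprintf("%s.c%02d", batch_label, seq_len(nch))
      gis_idx <- nch  # last channel reserved for the GIS pool
      diagnosis <- rep(NA_character_, nch)
      diagnosis[gis_idx] <- "GIS"
      n_real <- nch - 1L
      dx <- sample(rep(c("Control", "AD"), length.out = n_real))
      diagnosis[-gis_idx] <- dx
      gamma <- stats::rnorm(n_proteins, 0, sigma_batch)
      gamma_list[[batch_label]] <- gamma
      lambda <- stats::rnorm(nch, 0, sigma_channel)
      names(lambda) <- sample_ids
      severity <- stats::rnorm(nch) + as.numeric(diagnosis == "AD")
      severity[gis_idx] <- NA_real_
      names(severity) <- sample_ids
      age <- round(stats::rnorm(nch, 72, 6), 1)
      sex <- sample(c("M", "F"), nch, replace = TRUE)
      eps <- matrix(stats::rnorm(n_proteins * nch, 0, sigma_noise),
                    nrow = n_proteins)
      eps[, gis_idx] <- 0  # noiseless pool average
      log2v <- base + gamma +
        outer(delta, as.numeric(diagnosis == "AD" & !is.na(diagnosis))) +
        matrix(lambda, nrow = n_proteins, ncol = nch, byrow = TRUE) + eps
      cols[[batch_label]] <- log2v
      lambda_all <- c(lambda_all, lambda)
      sev_all <- c(sev_all, severity)
      sheet[[batch_label]] <- data.frame(
        sample_id = sample_ids,
        set_label = sprintf("Set%d", s),
        batch_label = batch_label,
        channel_label = sprintf("c%02d", seq_len(nch)),
        is_gis = seq_len(nch) == gis_idx,
        diagnosis = diagnosis,
        age = age, sex = sex,
        stringsAsFactors = FALSE)
    }
  }
  # center batch effects per protein within each set (zero mean over batches)
  for (s in seq_len(n_sets)) {
    bl <- grep(sprintf("^Set%d\\.", s), names(gamma_list), value = TRUE)
    g <- do.call(cbind, gamma_list[bl])
    g <- g - rowMeans(g)
    for (j in seq_along(bl)) {
      shift <- gamma_list[[bl[[j]]]] - g[, j]
      cols[[bl[[j]]]] <- cols[[bl[[j]]]] - shift
      gamma_list[[bl[[j]]]] <- g[, j]
    }
  }
  log2mat <- do.call(cbind, cols)
  sheet <- do.call(rbind, c(sheet, list(make.row.names = FALSE)))
  colnames(log2mat) <- sheet$sample_id
  rownames(log2mat) <- ids
  raw <- 2^log2mat

  # abundance-dependent missingness (left-censored flavor)
  if (missing_rate > 0) {
    for (j in seq_len(ncol(raw))) {
      rank_frac <- (rank(raw[, j], ties.method = "first") - 0.5) / nrow(raw)
      p_miss <- stats::plogis(stats::qlogis(missing_rate) +
                                missing_steepness * (0.5 - rank_frac))
      raw[stats::runif(nrow(raw)) < p_miss, j] <- NA_real_
    }
  }

  traits <- build_traits(sheet$sample_id, sev_all)
  truth <- list(effect_sizes = delta,
                batch_effects = do.call(cbind, gamma_list),
                channel_loadings = lambda_all,
                severity = sev_all,
                base = base)
  list(abundance = abundance_matrix(raw, "raw"),
       sheet = sheet, traits = traits, truth = truth)
}

# Trait construction: latent severity drives all six measures. Baselines
# chosen so that typical controls sit below the tTau/Abeta ratio inclusion
# threshold (0.226) and typical AD cases above it.
build_traits <- function(sample_ids, severity) {
  n <- length(severity)
  moca <- pmin(30, pmax(0, 28 - 6 * severity + stats::rnorm(n, 0, 2)))
  abeta <- pmax(100, 1400 - 400 * severity + stats::rnorm(n, 0, 150))
  ttau <- pmax(30, 250 + 130 * severity + stats::rnorm(n, 0, 40))
  ptau <- pmax(5, 50 + 25 * severity + stats::rnorm(n, 0, 8))
  ptau_plasma <- pmax(0.3, 2.5 + 1.2 * severity + stats::rnorm(n, 0, 0.4))
  df <- data.frame(sample_id = sample_ids,
                   MoCA = moca,
                   CSF_Abeta42 = abeta,
                   CSF_tTau = ttau,
                   CSF_pTau181 = ptau,
                   tTau_Abeta_ratio = ttau / abeta,
                   plasma_pTau181 = ptau_plasma,
                   stringsAsFactors = FALSE)
  df[is.na(severity), TRAIT_COLUMNS] <- NA_real_
  df
}

#' Simulate a reference brain co-expression network with planted modules
#'
#' Per module a latent standard-normal eigenprotein is drawn per sample;
#' each member protein row is `kme_target * e_m + sqrt(1 - kme_target^2) *
#' noise`. Grey proteins are pure noise. Brain traits (CERAD-like and
#' Braak-like pathology scores, an MMSE-like cognitive score) are linear
#' functions of the designated "matrisome-like" module's eigenprotein plus
#' noise, with MMSE oriented negatively.
#'
#' @param n_modules number of modules
#' @param proteins_per_module members per module
#' @param n_samples samples
#' @param kme_target target member-eigenprotein correlation, in (0,1)
#' @param n_grey number of unassigned pure-noise proteins
#' @param seed integer seed (required)
#' @param protein_ids optional explicit protein ids (length
#'   `n_modules * proteins_per_module + n_grey`); proteins are assigned to
#'   modules in the given order, grey last
#' @param matrisome_module module id designated as the matrisome-like
#'   disease module driving the brain traits (default the last module,
#'   or `"M42"` when 42 modules or more exist)
#' @return list with `abundance` (log2), `ref` (network_reference),
#'   `traits` (brain trait data.frame), `truth` (latent eigenproteins,
#'   membership, kme target)
#' @export
simulate_reference_brain <- function(n_modules = 44L,
                                     proteins_per_module = 25L,
                                     n_samples = 100L,
                                     kme_target = 0.6,
                                     n_grey = 200L,
                                     seed,
                                     protein_ids = NULL,
                                     matrisome_module = NULL) {
  if (missing(seed) || is.null(seed)) stopf("seed is required")
  if (kme_target <= 0 || kme_target >= 1) stopf("kme_target must be in (0, 1)")
  set.seed(stage_seed(seed, 23L))
  n_members <- n_modules * proteins_per_module
  n_total <- n_members + n_grey
  ids <- protein_ids %||% make_protein_ids(n_total, prefix = "B", sym_prefix = "BGN")
  stopifnot(length(ids) == n_total)
  module_ids <- sprintf("M%d", seq_len(n_modules))
  matrisome_module <- matrisome_module %||%
    (if (n_modules >= 42L) "M42" else module_ids[[n_modules]])
  sample_ids <- sprintf("brain%03d", seq_len(n_samples))

  latent <- matrix(stats::rnorm(n_modules * n_samples), nrow = n_modules,
                   dimnames = list(module_ids, sample_ids))
  latent <- t(scale(t(latent)))  # standardize rows

  membership <- stats::setNames(
    c(rep(module_ids, each = proteins_per_module), rep("grey", n_grey)), ids)
  noise_w <- sqrt(1 - kme_target^2)
  X <- matrix(stats::rnorm(n_total * n_samples), nrow = n_total,
              dimnames = list(ids, sample_ids))
  member_rows <- membership != "grey"
  X[member_rows, ] <- kme_target * latent[membership[member_rows], ] +
    noise_w * X[member_rows, ]
  X <- X + 10  # arbitrary log2 abundance offset

  eig <- t(apply(latent, 1L, function(v) (v - mean(v)) / stats::sd(v)))
  dimnames(eig) <- dimnames(latent)
  ref <- network_reference(membership, eig,
                           stats::setNames(ifelse(module_ids == matrisome_module,
                                                  "matrisome-like", "module"),
                                           module_ids))
  em <- eig[matrisome_module, ]
  traits <- data.frame(
    sample_id = sample_ids,
    CERAD = 1.5 + 0.9 * em + stats::rnorm(n_samples, 0, 0.4),
    Braak = 3 + 1.6 * em + stats::rnorm(n_samples, 0, 0.7),
    MMSE = pmin(30, pmax(0, 24 - 4.5 * em + stats::rnorm(n_samples, 0, 2))),
    stringsAsFactors = FALSE)
  truth <- list(latent = latent, true_membership = membership,
                kme_target = kme_target, matrisome_module = matrisome_module)
  list(abundance = abundance_matrix(X, "log2"),
       ref = ref, traits = traits, truth = truth)
}

#' Simulate label-free triplicate fractions (input / flow-through / enriched)
#'
#' Nine samples: DP1-3 (diluted plasma input), FT1-3 (depleted
#' flow-through), HP1-3 (affinity-enriched fraction). Designated
#' binder-like proteins are multiplied by `enrich_fold` in the HP columns;
#' designated high-abundance proteins are divided by `deplete_fold` there.
#' A configurable fraction of low-abundance proteins is set missing in DP
#' and FT only, emulating fraction-unique detections. Zeros are never
#' emitted; missing values are `NA`.
#'
#' @param n_proteins total proteins
#' @param n_hbp number of planted binder-like (enriched) proteins
#' @param n_abundant number of planted abundant (depleted) proteins
#' @param enrich_fold linear fold applied to binder-like proteins in HP
#' @param deplete_fold linear fold dividing abundant proteins in HP
#' @param sigma_noise log2 measurement noise SD
#' @param unique_frac fraction of low-abundance proteins detectable only in
#'   the enriched fraction
#' @param seed integer seed (required)
#' @return list with `abundance` (raw, 9 samples) and `truth`
#' @export
simulate_lfq_fractions <- function(n_proteins = 800L,
                                   n_hbp = 100L,
                                   n_abundant = 20L,
                                   enrich_fold = 4,
                                   deplete_fold = 4,
                                   sigma_noise = 0.2,
                                   unique_frac = 0.15,
                                   seed) {
  if (missing(seed) || is.null(seed)) stopf("seed is required")
  if (enrich_fold <= 1 || deplete_fold <= 1)
    stopf("enrich_fold and deplete_fold must be > 1")
  if (n_hbp + n_abundant > n_proteins)
    stopf("n_hbp + n_abundant must be <= n_proteins")
  set.seed(stage_seed(seed, 31L))
  ids <- make_protein_ids(n_proteins, prefix = "L", sym_prefix = "LGN")
  groups <- c("DP", "FT", "HP")
  sample_ids <- paste0(rep(groups, each = 3L), 1:3)
  base <- stats::rnorm(n_proteins, 20, 2.5)
  abundant_idx <- utils::head(order(base, decreasing = TRUE), n_abundant)
  low_idx <- utils::head(order(base), floor(unique_frac * n_proteins))
  hbp_idx <- sample(setdiff(seq_len(n_proteins), c(abundant_idx, low_idx)), n_hbp)
  hbp <- ids[hbp_idx]
  abundant <- ids[abundant_idx]
  log2v <- base + matrix(stats::rnorm(n_proteins * 9L, 0, sigma_noise), n_proteins)
  dimnames(log2v) <- list(ids, sample_ids)
  hp_cols <- grep("^HP", sample_ids)
  log2v[hbp, hp_cols] <- log2v[hbp, hp_cols] + log2(enrich_fold)
  log2v[abundant, hp_cols] <- log2v[abundant, hp_cols] - log2(deplete_fold)
  raw <- 2^log2v
  # fraction-unique detections: low-abundance proteins missing in DP/FT
  low <- ids[low_idx]
  raw[low, grep("^(DP|FT)", sample_ids)] <- NA_real_
  truth <- list(hbp = hbp, abundant = abundant, fraction_unique = low,
                enrich_fold = enrich_fold, deplete_fold = deplete_fold)
  list(abundance = abundance_matrix(raw, "raw"), truth = truth)
}

#' Build synthetic cell-type marker lists from a reference network
#'
#' Each cell type draws most of its markers from one designated module
#' (emulating cell-type-coherent co-expression modules) plus a sprinkling
#' of random background symbols.
#'
#' @param ref `network_reference`
#' @param celltypes character vector of cell-type names
#' @param modules module ids paired with `celltypes` (default: first
#'   modules in order)
#' @param purity fraction of each marker list drawn from its module
#' @param markers_per_type markers per cell type
#' @param seed integer seed
#' @return named list of upper-case gene symbol vectors
#' @export
simulate_celltype_markers <- function(ref,
                                      celltypes = c("astrocyte", "microglia",
                                                    "neuron", "oligodendrocyte",
                                                    "endothelial"),
                                      modules = NULL,
                                      purity = 0.8,
                                      markers_per_type = 20L,
                                      seed) {
  if (missing(seed) || is.null(seed)) stopf("seed is required")
  set.seed(stage_seed(seed, 41L))
  modules <- modules %||% ref$module_ids[seq_along(celltypes)]
  stopifnot(length(modules) == length(celltypes))
  all_syms <- gene_symbols(names(ref$membership))
  out <- list()
  for (i in seq_along(celltypes)) {
    mod_syms <- gene_symbols(names(ref$membership)[ref$membership == modules[[i]]])
    n_in <- min(length(mod_syms), round(purity * markers_per_type))
    n_out <- markers_per_type - n_in
    out[[celltypes[[i]]]] <- unique(c(sample(mod_syms, n_in),
                                      sample(all_syms, n_out)))
  }
  out
}

#' Build a synthetic GMT collection over a symbol universe
#'
#' Generates random gene sets plus, optionally, sets concentrated on given
#' symbol groups so that enrichment recovery is testable.
#'
#' @param symbols background symbol universe
#' @param n_random number of random sets
#' @param set_size size of each random set
#' @param planted named list of symbol vectors to include verbatim as sets
#' @param seed integer seed
#' @return gene-set collection (named list, `descriptions` attribute)
#' @export
simulate_gmt <- function(symbols, n_random = 20L, set_size = 25L,
                         planted = NULL, seed) {
  if (missing(seed) || is.null(seed)) stopf("seed is required")
  set.seed(stage_seed(seed, 43L))
  sets <- list()
  for (i in seq_len(n_random)) {
    sets[[sprintf("RANDOM_SET_%02d", i)]] <-
      sample(unique(toupper(symbols)), min(set_size, length(symbols)))
  }
  for (nm in names(planted)) sets[[nm]] <- unique(toupper(planted[[nm]]))
  attr(sets, "descriptions") <-
    stats::setNames(ifelse(names(sets) %in% names(planted), "planted", "random"),
                    names(sets))
  sets
}
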