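# Two-set meta-analysis, sample-inclusion filtering, Z-score transform and
# protein-trait correlation.

#' Filter samples by CSF biomarker ratio and cognition cutoffs
#'
#' AD cases are retained iff their CSF tTau/Abeta42 ratio exceeds
#' `ratio_thresh` and their MoCA score is below `moca_ad_max`; controls
#' are retained iff the ratio is at or below the threshold and MoCA is
#' above `moca_ctl_min`. Samples named in `exempt` (e.g. cases overlapping
#' both sets) and GIS channels are always retained.
#'
#' @param sheet sample sheet
#' @param traits trait table covering the non-exempt samples
#' @param ratio_thresh tTau/Abeta42 ratio cutoff separating AD-like from
#'   control-like biomarker profiles
#' @param moca_ad_max AD must score strictly below this MoCA value
#' @param moca_ctl_min controls must score strictly above this MoCA value
#' @param exempt sample ids always retained
#' @return filtered sample sheet
#' @export
sample_inclusion_filter <- function(sheet, traits, ratio_thresh = 0.226,
                                    moca_ad_max = 24, moca_ctl_min = 26,
                                    exempt = character(0)) {
  idx <- match(sheet$sample_id, traits$sample_id)
  ratio <- traits$tTau_Abeta_ratio[idx]
  moca <- traits$MoCA[idx]
  needs <- !sheet$is_gis & !(sheet$sample_id %in% exempt) &
    sheet$diagnosis %in% c("AD", "Control")
  lacking <- needs & (is.na(ratio) | is.na(moca))
  if (any(lacking))
    stopf("missing trait value(s) for sample(s): %s",
          paste(utils::head(sheet$sample_id[lacking], 5L), collapse = ", "))
  keep <- !needs |
    (sheet$diagnosis == "AD" & ratio > ratio_thresh & moca < moca_ad_max) |
    (sheet$diagnosis == "Control" & ratio <= ratio_thresh & moca > moca_ctl_min)
  keep[is.na(keep)] <- TRUE
  hep_log("inclusion", sprintf("sample filter kept %d of %d samples",
                               sum(keep), nrow(sheet)))
  sheet[keep, , drop = FALSE]
}

#' Fisher combined-probability meta p-value
#'
#' `X = -2 * sum(log(p_i))` is referred to a chi-square distribution with
#' `2k` degrees of freedom; a single p-value is returned unchanged.
#'
#' @param p_values vector of 1..k p-values in (0, 1]
#' @return combined p-value
#' @export
fisher_combine <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  if (!length(p_values)) return(NA_real_)
  if (any(p_values <= 0 | p_values > 1))
    stopf("p-values must lie in (0, 1] for Fisher combination")
  if (length(p_values) == 1L) return(p_values)
  X <- -2 * sum(log(p_values))
  stats::pchisq(X, df = 2L * length(p_values), lower.tail = FALSE)
}

#' Combine two per-set differential tables into a meta table
#'
#' Union of proteins; `mean_log2fc` averages the per-set log2
#' fold-changes over the sets where the protein was measured, and `meta_p`
#' Fisher-combines the per-set p-values over the sets where it was tested.
#' A protein present in a single set keeps that set's values (`n_sets =
#' 1`), so single-set proteins are retained rather than dropped.
#'
#' @param diff_set1,diff_set2 differential tables sharing the same
#'   contrast orientation (group2 vs group1)
#' @return data.frame: protein_id, mean_log2fc, meta_p, n_sets
#' @export
meta_table <- function(diff_set1, diff_set2) {
  ids <- union(diff_set1$protein_id, diff_set2$protein_id)
  i1 <- match(ids, diff_set1$protein_id)
  i2 <- match(ids, diff_set2$protein_id)
  fc <- cbind(diff_set1$log2fc[i1], diff_set2$log2fc[i2])
  pv <- cbind(diff_set1$p_value[i1], diff_set2$p_value[i2])
  mean_fc <- rowMeans(fc, na.rm = TRUE)
  mean_fc[is.nan(mean_fc)] <- NA_real_
  meta_p <- apply(pv, 1L, fisher_combine)
  n_sets <- rowSums(!is.na(pv))
  out <- data.frame(protein_id = ids, mean_log2fc = mean_fc, meta_p = meta_p,
                    n_sets = n_sets, row.names = NULL, stringsAsFactors = FALSE)
  # proteins untested in every set carry no evidence to combine
  out[out$n_sets > 0L, , drop = FALSE]
}

#' Row-wise Z-score transform
#'
#' Per protein row: subtract the mean and divide by the standard deviation
#' (n-1 denominator) over the observed entries; missing entries preserved.
#'
#' @param M log2-scale abundance matrix
#' @return z-scale abundance matrix
#' @export
zscore_rows <- function(M) {
  n_obs <- rowSums(!is.na(M))
  if (any(n_obs < 2L))
    stopf("protein %s has fewer than 2 observed values",
          rownames(M)[which(n_obs < 2L)[1L]])
  mu <- rowMeans(M, na.rm = TRUE)
  sdv <- sqrt(rowSums((M - mu)^2, na.rm = TRUE) / (n_obs - 1L))
  if (any(sdv == 0))
    stopf("protein %s has zero variance", rownames(M)[which(sdv == 0)[1L]])
  abundance_matrix((M - mu) / sdv, "z")
}

#' Pearson correlation with Student p-value
#'
#' Pairwise-complete Pearson correlation; the two-sided p-value comes from
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` with `n - 2` degrees of freedom.
#' Fewer than 3 complete pairs, or zero variance, yields an NA result.
#'
#' @param x,y numeric vectors of equal length
#' @return list with `r`, `p`, `n`
#' @export
pearson_cor_p <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n))
  r <- stats::cor(x[ok], y[ok])
  p <- cor_student_p(r, n)
  list(r = r, p = p, n = n)
}

cor_student_p <- function(r, n) {
  r2 <- pmin(r^2, 1)
  t <- abs(r) * sqrt((n - 2) / pmax(1 - r2, .Machine$double.eps))
  2 * stats::pt(-t, df = n - 2)
}

#' Protein x trait Pearson correlation table
#'
#' Per protein row of the Z-scored matrix and each AD-related trait
#' column, the pairwise-complete Pearson correlation with Student
#' p-value. Cells with fewer than 3 complete pairs (or a constant trait)
#' are NA.
#'
#' @param Z z-scale abundance matrix
#' @param traits trait table covering the matrix samples
#' @param trait_cols trait column names to correlate
#' @return list of protein x trait matrices `r`, `p`, `n`
#' @export
trait_correlation_table <- function(Z, traits, trait_cols = TRAIT_COLUMNS) {
  bad <- setdiff(trait_cols, colnames(traits))
  if (length(bad)) stopf("unknown trait column(s): %s", paste(bad, collapse = ", "))
  idx <- match(colnames(Z), traits$sample_id)
  Tm <- as.matrix(traits[idx, trait_cols, drop = FALSE])
  rownames(Tm) <- colnames(Z)
  r <- matrix(NA_real_, nrow(Z), length(trait_cols),
              dimnames = list(rownames(Z), trait_cols))
  p <- r; n <- r
  Xt <- t(Z)
  for (k in seq_along(trait_cols)) {
    y <- Tm[, k]
    if (all(is.na(y))) { n[, k] <- 0; next }
    nk <- rowSums(!is.na(Z[, !is.na(y), drop = FALSE]))
    suppressWarnings(
      rk <- as.vector(stats::cor(Xt, y, use = "pairwise.complete.obs")))
    rk[nk < 3L] <- NA_real_
    r[, k] <- rk
    n[, k] <- nk
    p[, k] <- ifelse(is.na(rk), NA_real_, cor_student_p(rk, nk))
  }
  list(r = r, p = p, n = n)
}

#' Select proteins significantly correlated with multiple traits
#'
#' @param C correlation table from [trait_correlation_table()]
#' @param min_significant minimum number of traits with `p < alpha`
#' @param alpha per-trait significance level (unadjusted by default, as
#'   the trait panel is small and fixed)
#' @return character vector of protein ids
#' @export
select_multitrait_proteins <- function(C, min_significant = 3L, alpha = 0.05) {
  if (min_significant > ncol(C$p))
    stopf("min_significant exceeds the number of traits")
  n_sig <- rowSums(C$p < alpha, na.rm = TRUE)
  rownames(C$p)[n_sig >= min_significant]
}
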