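# Normalization, filtering, imputation, median-polish batch correction and
# bootstrap covariate regression.

#' Channel-sum (sample-loading) normalization
#'
#' Each observed value is divided by the sum of observed intensities of its
#' sample (TMT channel) and multiplied by the maximum channel-specific
#' intensity sum, so all complete columns end with equal sums. Missing
#' values stay missing.
#'
#' @param M raw-scale abundance matrix
#' @return normalized-scale abundance matrix
#' @export
channel_sum_normalize <- function(M) {
  if (!abn_scale(M) %in% c("raw", "normalized"))
    stopf("channel_sum_normalize expects raw-scale abundances")
  sums <- colSums(M, na.rm = TRUE)
  empty <- colSums(!is.na(M)) == 0L
  if (any(empty))
    stopf("sample(s) with no observed values: %s",
          paste(colnames(M)[empty], collapse = ", "))
  out <- sweep(M, 2L, max(sums) / sums, `*`)
  abundance_matrix(out, "normalized")
}

#' Remove proteins exceeding a missingness fraction
#'
#' A protein is retained iff its missing fraction is `<= max_missing_frac`
#' (strictly greater is removed; at the default 0.5 a protein missing in
#' exactly half of the samples is kept). The sample set is unchanged.
#'
#' @param M abundance matrix
#' @param max_missing_frac maximum tolerated missing fraction, in 0..1
#' @return filtered abundance matrix
#' @export
filter_missingness <- function(M, max_missing_frac = 0.5) {
  stopifnot(max_missing_frac >= 0, max_missing_frac <= 1)
  frac <- rowMeans(is.na(M))
  keep <- frac <= max_missing_frac
  hep_log("filter", sprintf("missingness filter (<= %g): %d of %d proteins kept",
                            max_missing_frac, sum(keep), nrow(M)))
  out <- M[keep, , drop = FALSE]
  abundance_matrix(out, abn_scale(M))
}

#' Proteins detected in at least k of n replicates per group
#'
#' @param M abundance matrix
#' @param groups named character vector mapping sample id to group
#' @param k minimum number of member samples with an observed value
#' @return named list: per group, the character vector of detected proteins
#' @export
detect_in_k_of_n <- function(M, groups, k = 2L) {
  unknown <- setdiff(names(groups), colnames(M))
  if (length(unknown))
    stopf("unknown sample(s) in groups: %s", paste(unknown, collapse = ", "))
  out <- list()
  for (g in unique(groups)) {
    cols <- names(groups)[groups == g]
    if (k > length(cols)) stopf("k = %d exceeds size of group %s", k, g)
    n_obs <- rowSums(!is.na(M[, cols, drop = FALSE]))
    out[[g]] <- rownames(M)[n_obs >= k]
  }
  out
}

#' Downshifted Gaussian imputation of missing log2 values
#'
#' Per sample column with observed mean `m` and standard deviation `s`,
#' each missing cell is drawn from `Normal(m - downshift*s, (width*s)^2)`
#' — the left-censored convention for label-free data where missingness
#' concentrates at low abundance. Observed cells are untouched.
#'
#' @param M log2-scale abundance matrix
#' @param width SD of the imputation distribution as a fraction of the
#'   column SD
#' @param downshift downward shift in column SD units
#' @param seed integer seed (required)
#' @return complete log2-scale abundance matrix
#' @export
impute_downshifted <- function(M, width = 0.3, downshift = 1.8, seed) {
  if (missing(seed) || is.null(seed)) stopf("seed is required")
  if (abn_scale(M) != "log2") stopf("impute_downshifted expects log2 scale")
  set.seed(stage_seed(seed, 53L))
  out <- M
  for (j in seq_len(ncol(M))) {
    obs <- !is.na(M[, j])
    if (sum(obs) < 2L)
      stopf("column %s has fewer than 2 observed values", colnames(M)[j])
    miss <- which(!obs)
    if (!length(miss)) next
    m <- mean(M[obs, j]); s <- stats::sd(M[obs, j])
    out[miss, j] <- stats::rnorm(length(miss), m - downshift * s, width * s)
  }
  abundance_matrix(out, "log2")
}

#' Tunable median-polish batch correction anchored on internal standards
#'
#' Removes technical batch and sample-loading effects by an iterative
#' two-way median polish of log2 ratios. Each iteration (1) subtracts, per
#' protein and batch, the median over that batch's denominator samples
#' (the pooled GIS channels by default, or all batch samples), (2)
#' subtracts per-protein row medians, and (3) subtracts per-sample column
#' medians; iteration stops when the largest absolute adjustment drops
#' below `tol` or `max_iter` is reached. The polished residual is
#' reconstructed to abundance by adding back each protein's log2 median
#' over the original samples, so the output is a batch-corrected log2
#' abundance on the original scale. Missing cells are ignored by all
#' medians and remain missing. The procedure is (approximately) a fixed
#' point: re-applying it changes nothing beyond the convergence tolerance.
#'
#' @param M raw- or normalized-scale abundance matrix
#' @param sheet sample sheet covering `colnames(M)` (needs `batch_label`,
#'   `is_gis`)
#' @param denominator `"gis"` (default) or `"all_samples"`
#' @param max_iter maximum polish iterations
#' @param tol convergence tolerance on the largest absolute log2 adjustment
#' @param output_scale `"log2"` (default) or `"abundance"`
#' @return batch-corrected abundance matrix
#' @export
tampor <- function(M, sheet, denominator = c("gis", "all_samples"),
                   max_iter = 250L, tol = 1e-8,
                   output_scale = c("log2", "abundance")) {
  denominator <- match.arg(denominator)
  output_scale <- match.arg(output_scale)
  stopifnot(tol > 0, max_iter >= 1L)
  if (!abn_scale(M) %in% c("raw", "normalized"))
    stopf("tampor expects positive raw/normalized abundances")
  sheet <- sheet[match(colnames(M), sheet$sample_id), , drop = FALSE]
  if (anyNA(sheet$sample_id)) stopf("sample sheet does not cover all matrix columns")
  batches <- split(seq_len(ncol(M)), sheet$batch_label)
  denom_cols <- lapply(batches, function(idx) {
    if (denominator == "gis") idx[sheet$is_gis[idx]] else idx
  })
  empty <- names(denom_cols)[lengths(denom_cols) == 0L]
  if (length(empty))
    stopf("batch(es) lacking denominator samples: %s", paste(empty, collapse = ", "))

  R <- log2(M)
  attr(R, "scale") <- NULL
  # ratio to the per-(protein, batch) denominator median; proteins absent
  # from a batch's denominator cannot be ratio-anchored there and become NA
  for (b in names(batches)) {
    d <- row_medians(R[, denom_cols[[b]], drop = FALSE])
    R[, batches[[b]]] <- R[, batches[[b]], drop = FALSE] - d
  }
  # two-way median polish: alternately sweep per-protein row medians and
  # per-sample column medians out of the log2 ratios
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    r <- row_medians(R)
    r[is.na(r)] <- 0
    R <- R - r
    cc <- col_medians(R)
    cc[is.na(cc)] <- 0
    R <- sweep(R, 2L, cc)
    delta <- max(abs(r), abs(cc))
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warnf("median polish did not converge in %d iterations (last adjustment %.3g)",
          max_iter, delta)
  out <- R + row_medians(log2(M))
  hep_log("tampor", sprintf("polish %s after %d iteration(s), %d proteins x %d samples",
                            if (converged) "converged" else "stopped", iter,
                            nrow(M), ncol(M)))
  if (output_scale == "abundance") {
    abundance_matrix(2^out, "normalized")
  } else {
    abundance_matrix(out, "log2")
  }
}

#' Bootstrap covariate regression of log2 abundances
#'
#' Per protein, an ordinary least-squares model of abundance on protected
#' terms plus nuisance covariates is fit over complete cases; coefficients
#' are averaged over bootstrap resamples of samples (stratified by batch so
#' the batch design stays estimable; rank-deficient resamples are redrawn).
#' The corrected value is the observed value minus each covariate term's
#' averaged coefficient times the centered covariate; protected-term
#' contributions (e.g. diagnosis) are never removed.
#'
#' @param M log2-scale abundance matrix
#' @param sheet sample sheet with the covariate columns
#' @param covariates names of sheet columns to regress out (categoricals
#'   are one-hot encoded against the first level)
#' @param protect names of sheet columns whose effects are preserved
#' @param n_boot number of bootstrap resamples; `n_boot = 1` with
#'   `full_sample = TRUE` reduces to plain OLS correction
#' @param seed integer seed (required)
#' @param full_sample fit once on the full sample instead of resampling
#' @return corrected log2-scale abundance matrix
#' @export
bootstrap_covariate_regress <- function(M, sheet, covariates,
                                        protect = "diagnosis",
                                        n_boot = 100L, seed,
                                        full_sample = FALSE) {
  if (missing(seed) || is.null(seed)) stopf("seed is required")
  if (abn_scale(M) != "log2") stopf("bootstrap_covariate_regress expects log2 scale")
  if (length(intersect(covariates, protect)))
    stopf("protected and covariate names collide: %s",
          paste(intersect(covariates, protect), collapse = ", "))
  sheet <- sheet[match(colnames(M), sheet$sample_id), , drop = FALSE]
  for (v in c(covariates, protect)) {
    if (!v %in% colnames(sheet)) stopf("column %s absent from sample sheet", v)
  }
  set.seed(stage_seed(seed, 61L))

  vars <- c(protect, covariates)
  mf <- sheet[, vars, drop = FALSE]
  for (v in vars) if (is.character(mf[[v]])) mf[[v]] <- factor(mf[[v]])
  form <- stats::as.formula(paste("~", paste(vars, collapse = " + ")))
  X <- stats::model.matrix(form, data = mf)
  # columns of the design belonging to nuisance covariates
  assign_idx <- attr(X, "assign")
  cov_terms <- which(vars %in% covariates)
  cov_cols <- which(assign_idx %in% cov_terms)
  p <- ncol(X)
  strata <- split(seq_len(ncol(M)), sheet$batch_label)

  draw_idx <- function() {
    unlist(lapply(strata, function(s) sample(s, length(s), replace = TRUE)),
           use.names = FALSE)
  }
  boot_sets <- if (full_sample) {
    replicate(n_boot, seq_len(ncol(M)), simplify = FALSE)
  } else {
    replicate(n_boot, draw_idx(), simplify = FALSE)
  }

  out <- M
  n_skipped <- 0L
  complete_rows <- rowSums(is.na(M)) == 0L
  centered_cov <- scale(X[, cov_cols, drop = FALSE], center = TRUE, scale = FALSE)

  correct_rows <- function(rows, obs_cols) {
    Xo <- X[obs_cols, , drop = FALSE]
    if (length(obs_cols) <= p || qr(Xo)$rank < p) {
      n_skipped <<- n_skipped + length(rows)
      return(invisible(NULL))
    }
    Y <- t(M[rows, obs_cols, drop = FALSE])
    beta_sum <- matrix(0, nrow = p, ncol = length(rows)); n_ok <- 0L
    for (idx in boot_sets) {
      idx2 <- idx[idx %in% obs_cols]
      pos <- match(idx2, obs_cols)
      Xb <- Xo[pos, , drop = FALSE]
      if (qr(Xb)$rank < p) {
        ok <- FALSE
        for (try in 1:10) {
          pos <- sample(seq_along(obs_cols), length(obs_cols), replace = TRUE)
          Xb <- Xo[pos, , drop = FALSE]
          if (qr(Xb)$rank == p) { ok <- TRUE; break }
        }
        if (!ok) next
      }
      beta_sum <- beta_sum + qr.coef(qr(Xb), Y[pos, , drop = FALSE])
      n_ok <- n_ok + 1L
    }
    if (n_ok == 0L) { n_skipped <<- n_skipped + length(rows); return(invisible(NULL)) }
    beta <- beta_sum / n_ok
    adj <- centered_cov %*% beta[cov_cols, , drop = FALSE]  # samples x rows
    out[rows, ] <<- out[rows, , drop = FALSE] - t(adj)
    invisible(NULL)
  }

  # fast path: all complete proteins share one design
  if (any(complete_rows)) correct_rows(which(complete_rows), seq_len(ncol(M)))
  # per-pattern path for proteins with missing values
  if (any(!complete_rows)) {
    patt <- apply(!is.na(M[!complete_rows, , drop = FALSE]), 1L, paste, collapse = "")
    rows_by_patt <- split(which(!complete_rows), patt)
    for (rows in rows_by_patt) {
      obs_cols <- which(!is.na(M[rows[[1L]], ]))
      correct_rows(rows, obs_cols)
    }
  }
  if (n_skipped > 0L)
    warnf("%d protein(s) left uncorrected (too few complete cases for the design)",
          n_skipped)
  hep_log("regress", sprintf("bootstrap regression (%d resamples) on %d proteins, %d covariate column(s)",
                             n_boot, nrow(M) - n_skipped, length(cov_cols)))
  abundance_matrix(out, "log2")
}
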