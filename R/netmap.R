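# Projection of a proteome onto a reference co-expression network:
# biweight midcorrelation, module eigenproteins, kME assignment,
# module-trait correlation, and overrepresentation tests.

# Robust biweight transform of one vector: median-centered, Tukey-biweight
# weighted, normalized to unit length. MAD here is the raw median absolute
# deviation (no consistency constant), with the tuning constant fixed at 9
# MADs; a zero-MAD vector falls back to Pearson-style standardization.
bicor_transform <- function(x) {
  med <- stats::median(x)
  madv <- stats::median(abs(x - med))
  if (madv == 0) {
    ctr <- x - mean(x)
    s <- sqrt(sum(ctr^2))
    if (s == 0) return(rep(NA_real_, length(x)))
    return(ctr / s)
  }
  u <- (x - med) / (9 * madv)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  xt <- (x - med) * w
  s <- sqrt(sum(xt^2))
  if (s == 0) {
    ctr <- x - mean(x)
    return(ctr / sqrt(sum(ctr^2)))
  }
  xt / s
}

#' Biweight midcorrelation
#'
#' Robust correlation that down-weights observations far from the median
#' (Tukey biweight with the tuning constant at 9 raw MADs). When a
#' vector's MAD is zero, Pearson centering/scaling is used for that vector.
#' Computed over pairwise-complete observations; fewer than 3 yield `NA`.
#'
#' @param x,y numeric vectors of equal length
#' @return correlation in -1..1
#' @export
bicor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) return(NA_real_)
  xt <- bicor_transform(x[ok])
  yt <- bicor_transform(y[ok])
  if (anyNA(xt) || anyNA(yt)) return(NA_real_)
  min(1, max(-1, sum(xt * yt)))
}

# Row-wise bicor between two matrices sharing columns (samples). Rows with
# no missing values use the vectorized transform; rows with NAs fall back
# to pairwise bicor.
bicor_matrix <- function(X, Y) {
  stopifnot(ncol(X) == ncol(Y))
  tx <- t(apply(X, 1L, function(r) if (anyNA(r)) rep(NA_real_, length(r)) else bicor_transform(r)))
  ty <- t(apply(Y, 1L, function(r) if (anyNA(r)) rep(NA_real_, length(r)) else bicor_transform(r)))
  out <- matrix(NA_real_, nrow(X), nrow(Y), dimnames = list(rownames(X), rownames(Y)))
  x_ok <- !apply(tx, 1L, anyNA)
  y_ok <- !apply(ty, 1L, anyNA)
  if (any(x_ok) && any(y_ok))
    out[x_ok, y_ok] <- tcrossprod(tx[x_ok, , drop = FALSE], ty[y_ok, , drop = FALSE])
  for (i in which(!x_ok)) for (j in seq_len(nrow(Y)))
    out[i, j] <- bicor(X[i, ], Y[j, ])
  for (j in which(!y_ok)) for (i in which(x_ok))
    out[i, j] <- bicor(X[i, ], Y[j, ])
  out[] <- pmin(1, pmax(-1, out))
  out
}

#' Module eigenprotein (first principal component of a module)
#'
#' Member rows are standardized per protein (missing member values imputed
#' by the protein's row mean first), the first principal component across
#' samples is extracted and standardized to mean 0 / SD 1, and its sign is
#' chosen so that it correlates positively with the column mean of the
#' standardized member data (so higher eigenprotein means higher module
#' abundance).
#'
#' @param M log2-scale abundance matrix
#' @param member_ids module member protein ids (>= 2 with data)
#' @return named sample-length numeric vector
#' @export
module_eigenprotein <- function(M, member_ids) {
  member_ids <- intersect(member_ids, rownames(M))
  X <- M[member_ids, , drop = FALSE]
  usable <- rowSums(!is.na(X)) >= 2L & apply(X, 1L, stats::sd, na.rm = TRUE) > 0
  X <- X[usable, , drop = FALSE]
  if (nrow(X) < 2L) stopf("fewer than 2 usable module members")
  for (i in seq_len(nrow(X))) {
    na <- is.na(X[i, ])
    if (any(na)) X[i, na] <- mean(X[i, ], na.rm = TRUE)
  }
  Xs <- t(scale(t(X)))
  sv <- svd(Xs, nu = 0L, nv = 1L)
  e <- sv$v[, 1L]
  e <- (e - mean(e)) / stats::sd(e)
  if (stats::cor(e, colMeans(Xs)) < 0) e <- -e
  stats::setNames(e, colnames(M))
}

#' Assign proteins to reference network modules by kME
#'
#' Per protein the biweight midcorrelation (kME) to every module
#' eigenprotein is computed; the protein is assigned to the module with
#' the highest positive kME if that value is at least `kme_min`
#' (inclusive), otherwise to `"grey"`. Ties break to the lowest module
#' index. In `mode = "reference"` the reference eigenproteins are used
#' directly (query and reference must share samples); in `mode =
#' "recompute"` eigenproteins are recomputed from the reference membership
#' on the query matrix, for projecting a proteome measured on different
#' samples.
#'
#' @param M log2-scale abundance matrix
#' @param ref `network_reference`
#' @param kme_min minimum kME for a module assignment (inclusive)
#' @param mode `"reference"` or `"recompute"`
#' @return data.frame: protein_id, assigned_module, kme_best; the full
#'   protein x module kME matrix is attached as attribute `kme_all`
#' @export
assign_to_modules <- function(M, ref, kme_min = 0.30,
                              mode = c("reference", "recompute")) {
  mode <- match.arg(mode)
  if (mode == "reference") {
    shared <- intersect(colnames(M), colnames(ref$eigenproteins))
    if (length(shared) < 3L) stopf("no shared samples between matrix and reference")
    E <- ref$eigenproteins[, shared, drop = FALSE]
    X <- M[, shared, drop = FALSE]
  } else {
    X <- M
    E <- matrix(NA_real_, length(ref$module_ids), ncol(M),
                dimnames = list(ref$module_ids, colnames(M)))
    for (m in ref$module_ids) {
      members <- intersect(names(ref$membership)[ref$membership == m], rownames(M))
      if (length(members) >= 2L)
        E[m, ] <- tryCatch(module_eigenprotein(M, members),
                           error = function(e) rep(NA_real_, ncol(M)))
    }
    keep <- rowSums(!is.na(E)) > 0L
    if (!any(keep)) stopf("no module eigenprotein could be recomputed on the query matrix")
    E <- E[keep, , drop = FALSE]
  }
  kme <- bicor_matrix(X, E)
  best_idx <- apply(kme, 1L, function(r) {
    if (all(is.na(r))) return(NA_integer_)
    which.max(replace(r, is.na(r), -Inf))  # ties -> lowest module index
  })
  kme_best <- kme[cbind(seq_len(nrow(kme)), best_idx)]
  assigned <- ifelse(!is.na(kme_best) & kme_best > 0 & kme_best >= kme_min,
                     colnames(kme)[best_idx], "grey")
  out <- data.frame(protein_id = rownames(M),
                    assigned_module = assigned,
                    kme_best = kme_best,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "kme_all") <- kme
  out
}

#' Module eigenprotein vs trait biweight midcorrelation
#'
#' @param eigen module x sample eigenprotein matrix
#' @param traits data.frame with `sample_id` plus numeric trait columns
#' @param trait_cols trait columns to use (default: all numeric columns)
#' @return list of module x trait matrices `r`, `p`, `n` (Student p,
#'   df = n - 2); constant traits give NA
#' @export
module_trait_bicor <- function(eigen, traits, trait_cols = NULL) {
  trait_cols <- trait_cols %||%
    setdiff(colnames(traits)[vapply(traits, is.numeric, TRUE)], "sample_id")
  idx <- match(colnames(eigen), traits$sample_id)
  r <- matrix(NA_real_, nrow(eigen), length(trait_cols),
              dimnames = list(rownames(eigen), trait_cols))
  p <- r; n <- r
  for (k in seq_along(trait_cols)) {
    y <- traits[[trait_cols[[k]]]][idx]
    for (m in seq_len(nrow(eigen))) {
      x <- eigen[m, ]
      ok <- !is.na(x) & !is.na(y)
      n[m, k] <- sum(ok)
      if (sum(ok) < 3L || stats::sd(y[ok]) == 0) next
      r[m, k] <- bicor(x, y)
      if (!is.na(r[m, k])) p[m, k] <- cor_student_p(r[m, k], sum(ok))
    }
  }
  list(r = r, p = p, n = n)
}

#' One-tailed Fisher exact (hypergeometric) overrepresentation test
#'
#' `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)` (overlap of a
#' foreground of size `n` with a set of size `K` in a background of size
#' `N`), plus the standardized hypergeometric deviate `z = (k - mu) /
#' sigma` with `mu = n*K/N` and `sigma^2 = n*K*(N-K)*(N-n) /
#' (N^2*(N-1))`; a degenerate margin (`sigma = 0`) gives `z = 0`.
#' Vectorized over its arguments.
#'
#' @param k observed overlap
#' @param K set size within the background
#' @param n foreground size
#' @param N background size
#' @return data.frame with columns `p`, `z`, `expected`
#' @export
fisher_exact_one_tailed <- function(k, K, n, N) {
  len <- max(length(k), length(K), length(n), length(N))
  k <- as.numeric(rep_len(k, len)); K <- as.numeric(rep_len(K, len))
  n <- as.numeric(rep_len(n, len)); N <- as.numeric(rep_len(N, len))
  if (any(k < 0 | K < 0 | n < 0 | N < 1 | k > pmin(K, n) | K > N | n > N))
    stopf("inconsistent hypergeometric margins")
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  mu <- n * K / N
  sig2 <- n * K * (N - K) * (N - n) / (N^2 * pmax(N - 1, 1))
  z <- ifelse(sig2 > 0, (k - mu) / sqrt(sig2), 0)
  data.frame(p = p, z = z, expected = mu)
}

# Shared enrichment-table builder: one row per (set, foreground) pair.
enrichment_rows <- function(set_id, fg_label, set_members, fg, background) {
  k <- length(intersect(fg, set_members))
  K <- length(set_members)
  n <- length(fg)
  N <- length(background)
  fe <- fisher_exact_one_tailed(k, K, n, N)
  data.frame(set_id = set_id, foreground = fg_label,
             overlap_k = k, set_size_K = K, foreground_n = n,
             background_N = N, expected_mu = fe$expected,
             z_score = fe$z, p_one_tailed = fe$p,
             stringsAsFactors = FALSE)
}

#' Module overrepresentation of up/down protein lists
#'
#' Per module and direction, a one-tailed Fisher exact test of the overlap
#' between the foreground list and the module members (both intersected
#' with the background); BH adjustment across modules within each
#' direction.
#'
#' @param fg_up,fg_down protein ids increased/decreased (must be subsets
#'   of `background`); either may be empty
#' @param ref `network_reference`
#' @param background protein id universe
#' @return enrichment data.frame with `q_bh` per direction
#' @export
module_overlap_fet <- function(fg_up, fg_down, ref, background) {
  offenders <- setdiff(c(fg_up, fg_down), background)
  if (length(offenders))
    stopf("foreground not a subset of background: %s",
          paste(utils::head(offenders, 5L), collapse = ", "))
  modules <- ref$module_ids
  out <- list()
  for (dir in c("up", "down")) {
    fg <- intersect(if (dir == "up") fg_up else fg_down, background)
    rows <- lapply(modules, function(m) {
      members <- intersect(names(ref$membership)[ref$membership == m], background)
      enrichment_rows(m, dir, members, fg, background)
    })
    tab <- do.call(rbind, rows)
    tab$q_bh <- bh_adjust(tab$p_one_tailed)
    out[[dir]] <- tab
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Cell-type marker overrepresentation per module
#'
#' Cross-references the gene symbols of each module with cell-type marker
#' lists via a one-tailed Fisher exact test; BH adjustment across all
#' module x cell-type cells. Symbols are matched case-insensitively.
#'
#' @param ref `network_reference`
#' @param markers named list of marker gene symbol vectors per cell type
#' @param background protein ids or gene symbols forming the universe
#' @return enrichment data.frame (`set_id` = module, `foreground` = cell
#'   type) with `q_bh`
#' @export
celltype_fet <- function(ref, markers, background) {
  if (!length(background)) stopf("background is empty")
  if (any(!lengths(markers))) stopf("marker lists must be non-empty")
  bg_syms <- unique(gene_symbols(background))
  out <- list()
  for (m in ref$module_ids) {
    mod_syms <- intersect(unique(gene_symbols(
      names(ref$membership)[ref$membership == m])), bg_syms)
    for (ct in names(markers)) {
      fg <- intersect(unique(toupper(markers[[ct]])), bg_syms)
      out[[paste(m, ct)]] <- enrichment_rows(m, ct, mod_syms, fg, bg_syms)
    }
  }
  tab <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  tab$q_bh <- bh_adjust(tab$p_one_tailed)
  tab
}
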