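# Two-group differential abundance, multiple-testing correction, threshold
# filters, fraction-comparison ANOVA and supervised clustering.

#' Per-protein two-group Student t-test table
#'
#' Vectorized two-sided pooled-variance (classical Student) t-test per
#' protein over the observed values of each group; `welch = TRUE` switches
#' to the unequal-variance form. Proteins with fewer than `min_per_group`
#' observed values in either group receive `NA` statistics and are
#' excluded from the Benjamini-Hochberg family. `log2fc` is mean(group2) -
#' mean(group1) in log2 space, so with group1 = Control and group2 = AD it
#' is the AD-vs-Control log2 fold change.
#'
#' @param M log2-scale abundance matrix
#' @param groups named character/factor vector over samples with exactly
#'   the two labels `g1` and `g2`
#' @param g1,g2 group labels (reference first)
#' @param min_per_group minimum observed values per group to test
#' @param welch use the Welch unequal-variance test
#' @param alpha significance level used only to annotate `direction`
#' @return data.frame: protein_id, n_group1, n_group2, log2fc, t_stat,
#'   p_value, q_value, direction
#' @export
student_ttest_table <- function(M, groups, g1 = "Control", g2 = "AD",
                                min_per_group = 2L, welch = FALSE,
                                alpha = 0.05) {
  if (!all(c(g1, g2) %in% groups))
    stopf("group label(s) absent from groups map: %s",
          paste(setdiff(c(g1, g2), groups), collapse = ", "))
  c1 <- names(groups)[groups == g1]
  c2 <- names(groups)[groups == g2]
  missing_cols <- setdiff(c(c1, c2), colnames(M))
  if (length(missing_cols))
    stopf("samples not in matrix: %s", paste(missing_cols, collapse = ", "))
  X1 <- M[, c1, drop = FALSE]
  X2 <- M[, c2, drop = FALSE]
  n1 <- rowSums(!is.na(X1)); n2 <- rowSums(!is.na(X2))
  m1 <- rowMeans(X1, na.rm = TRUE); m2 <- rowMeans(X2, na.rm = TRUE)
  v1 <- rowSums((X1 - m1)^2, na.rm = TRUE) / pmax(n1 - 1L, 1L)
  v2 <- rowSums((X2 - m2)^2, na.rm = TRUE) / pmax(n2 - 1L, 1L)
  diff <- m2 - m1
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
    tt <- diff / sqrt(se2)
    zero_var <- se2 == 0
  } else {
    sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
    tt <- diff / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2L
    zero_var <- sp2 == 0
  }
  p <- 2 * stats::pt(-abs(tt), df)
  # degenerate zero-variance rows: identical groups give t = 0, p = 1
  degen <- !is.na(zero_var) & zero_var
  degen[is.na(degen)] <- FALSE
  tt[degen] <- ifelse(diff[degen] == 0, 0, sign(diff[degen]) * Inf)
  p[degen] <- ifelse(diff[degen] == 0, 1, 0)
  untested <- n1 < min_per_group | n2 < min_per_group
  tt[untested] <- NA_real_; p[untested] <- NA_real_
  diff[untested] <- ifelse(n1[untested] >= 1L & n2[untested] >= 1L,
                           diff[untested], NA_real_)
  q <- bh_adjust(p)
  direction <- rep("unchanged", nrow(M))
  direction[!is.na(p) & p < alpha & diff > 0] <- "up"
  direction[!is.na(p) & p < alpha & diff < 0] <- "down"
  data.frame(protein_id = rownames(M),
             n_group1 = n1, n_group2 = n2,
             log2fc = diff, t_stat = tt,
             p_value = p, q_value = q,
             direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `NA` entries are passed through and do not count towards the family
#' size; q-values are capped at 1 and never smaller than their p-value.
#'
#' @param p vector of p-values in 0..1 (NA allowed)
#' @return vector of BH q-values in the original order
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stopf("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Partition a differential table at significance/fold thresholds
#'
#' Strict inequalities throughout: up = statistic `< p_max` and `log2fc >
#' log2(fc_min_fold)`; down symmetric. The fold threshold is on the linear
#' scale (fold 2 means |log2fc| > 1) and skipped when `fc_min_fold` is
#' `NULL`.
#'
#' @param table differential table from [student_ttest_table()]
#' @param p_max p (or q) threshold, exclusive
#' @param fc_min_fold minimum linear fold change (> 1), or `NULL`
#' @param use_q threshold the BH q-value instead of the raw p-value
#' @return list with `up` and `down` protein id vectors
#' @export
threshold_filter <- function(table, p_max = 0.05, fc_min_fold = NULL,
                             use_q = FALSE) {
  if (!is.null(fc_min_fold) && fc_min_fold <= 1)
    stopf("fc_min_fold must be > 1")
  stat <- if (use_q) table$q_value else table$p_value
  sig <- !is.na(stat) & stat < p_max
  lfc_min <- if (is.null(fc_min_fold)) 0 else log2(fc_min_fold)
  up <- sig & !is.na(table$log2fc) & table$log2fc > lfc_min
  down <- sig & !is.na(table$log2fc) & table$log2fc < -lfc_min
  list(up = table$protein_id[up], down = table$protein_id[down])
}

#' One-way ANOVA with Tukey HSD post-hoc pairwise p-values
#'
#' @param values numeric response vector
#' @param groups factor/character group labels (>= 2 observations per
#'   level, nonzero within-group variance overall)
#' @return data.frame: pair, diff, p_adj, plus the ANOVA F and p as
#'   attributes `f_stat` / `f_p`
#' @export
anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  if (any(table(groups) < 2L)) stopf("each group needs >= 2 observations")
  rss <- sum(unlist(tapply(values, groups, function(v) (v - mean(v))^2)))
  if (rss <= 0)
    stopf("zero within-group variance; Tukey intervals undefined")
  df <- data.frame(y = values, g = groups)
  fit <- stats::aov(y ~ g, data = df)
  an <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit)$g
  out <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                    p_adj = tk[, "p adj"], row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "f_stat") <- an[1L, "F value"]
  attr(out, "f_p") <- an[1L, "Pr(>F)"]
  out
}

#' Supervised hierarchical clustering of samples on a protein subset
#'
#' Agglomerative clustering of samples with Euclidean distance and
#' complete linkage on the given protein rows (which must be complete:
#' impute or drop missing values first).
#'
#' @param M log2-scale abundance matrix
#' @param protein_subset protein ids to cluster on
#' @param distance distance metric (euclidean)
#' @param linkage agglomeration method (complete)
#' @return list with `hclust` (the fitted tree), `order` (sample ids in
#'   dendrogram order) and `heights` (merge heights, non-decreasing)
#' @export
supervised_clustering <- function(M, protein_subset, distance = "euclidean",
                                  linkage = "complete") {
  if (!length(protein_subset)) stopf("protein subset is empty")
  missing_ids <- setdiff(protein_subset, rownames(M))
  if (length(missing_ids))
    stopf("protein(s) not in matrix: %s", paste(utils::head(missing_ids, 3L), collapse = ", "))
  sub <- M[protein_subset, , drop = FALSE]
  if (anyNA(sub)) stopf("subset has missing values; impute or drop first")
  if (ncol(sub) == 1L) {
    return(list(hclust = NULL, order = colnames(sub), heights = numeric(0)))
  }
  d <- stats::dist(t(sub), method = distance)
  hc <- stats::hclust(d, method = linkage)
  list(hclust = hc, order = colnames(sub)[hc$order], heights = hc$height)
}
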