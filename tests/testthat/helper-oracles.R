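# Independent oracles, kept deliberately naive: each recomputes a quantity
# from first principles so implementation and check never share code.

# textbook pooled-variance two-sample t-test
oracle_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(y) - mean(x)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), n1 + n2 - 2))
}

# Benjamini-Hochberg step-up written out literally
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# one-tailed hypergeometric P(X >= k) by direct enumeration over choose()
oracle_hyper <- function(k, K, n, N) {
  lo <- max(0, n - (N - K))
  hi <- min(K, n)
  support <- lo:hi
  probs <- choose(K, support) * choose(N - K, n - support) / choose(N, n)
  sum(probs[support >= k])
}

# brute-force agglomerative complete-linkage on a small sample set;
# returns the sorted merge heights
oracle_complete_linkage_heights <- function(X) {
  # X: samples x features
  clusters <- as.list(seq_len(nrow(X)))
  D <- as.matrix(dist(X))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      d <- max(D[clusters[[i]], clusters[[j]]])
      if (d < best_d) { best_d <- d; best <- c(i, j) }
    }
    heights <- c(heights, best_d)
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  sort(heights)
}

# Tukey HSD adjusted p for one pair, from the studentized range distribution
oracle_tukey_pair <- function(values, groups, g_a, g_b) {
  groups <- factor(groups)
  k <- nlevels(groups)
  ns <- table(groups)
  means <- tapply(values, groups, mean)
  df_err <- length(values) - k
  mse <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2))) / df_err
  se <- sqrt(mse / 2 * (1 / ns[[g_a]] + 1 / ns[[g_b]]))
  q_stat <- abs(means[[g_a]] - means[[g_b]]) / se
  ptukey(q_stat, k, df_err, lower.tail = FALSE)
}

# small random simulated TMT fixture
tiny_study <- function(seed, ...) {
  args <- modifyList(list(n_sets = 1L, batches_per_set = 3L,
                          channels_per_batch = 6L, n_proteins = 60L,
                          n_effect_proteins = 10L, missing_rate = 0,
                          seed = seed), list(...))
  do.call(simulate_tmt_plasma, args)
}

expect_silent_log <- function(expr) {
  suppressMessages(suppressWarnings(expr))
}

TRAIT_COLUMNS_FOR_TEST <- c("MoCA", "CSF_Abeta42", "CSF_tTau", "CSF_pTau181",
                            "tTau_Abeta_ratio", "plasma_pTau181")
make_protein_ids <- hepnet:::make_protein_ids
cor_student_p_for_test <- hepnet:::cor_student_p
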