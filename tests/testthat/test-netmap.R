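# Biweight midcorrelation, eigenproteins, kME module assignment, and
# overrepresentation tests.

test_that("bicor self-correlation is 1 and tracks Pearson on clean data", {
  set.seed(31)
  x <- rnorm(50)
  expect_equal(bicor(x, x), 1)
  expect_equal(bicor(x, -x), -1)
  # bivariate normal, rho = 0.5: bicor close to Pearson
  n <- 500
  a <- rnorm(n); b <- 0.5 * a + sqrt(0.75) * rnorm(n)
  expect_lt(abs(bicor(a, b) - cor(a, b)), 0.05)
})

test_that("bicor resists a single gross outlier that breaks Pearson", {
  set.seed(37)
  n <- 100
  x <- rnorm(n); y <- 0.6 * x + 0.8 * rnorm(n)
  x2 <- c(x, 100); y2 <- c(y, -100)   # one 100-SD contaminated point
  expect_lt(abs(bicor(x2, y2) - bicor(x, y)), 0.05)
  expect_gt(abs(cor(x2, y2) - cor(x, y)), 0.2)
})

test_that("bicor handles degenerate inputs via the Pearson fallback", {
  expect_true(is.na(bicor(c(1, 2), c(3, 4))))           # n < 3
  # zero MAD (more than half ties) falls back to Pearson scaling
  x <- c(rep(0, 6), 1, 2, 3, 4)
  y <- 2 * x + 1
  expect_equal(bicor(x, y), 1, tolerance = 1e-12)
  # pairwise-complete handling
  x3 <- c(NA, rnorm(20)); y3 <- c(1, 0.9 * x3[-1] + 0.1 * rnorm(20))
  expect_equal(bicor(x3, y3), bicor(x3[-1], y3[-1]))
})

test_that("module eigenprotein recovers rank-1 structure and latent factors", {
  ids <- make_protein_ids(6)
  prof <- rnorm(10)
  vals <- matrix(rep(prof, each = 6), 6, dimnames = list(ids, sprintf("s%d", 1:10)))
  vals <- vals * c(1, 2, 1, 3, 1, 2) + c(0, 5, 1, 2, 3, 4)
  M <- abundance_matrix(vals, "log2")
  e <- module_eigenprotein(M, ids)
  expect_equal(abs(cor(e, prof)), 1, tolerance = 1e-10)
  expect_gt(cor(e, prof), 0)   # sign follows the member average
  expect_equal(mean(e), 0, tolerance = 1e-12)
  expect_equal(sd(e), 1, tolerance = 1e-12)

  # flipping all member rows flips the eigenprotein
  flipped <- abundance_matrix(-vals, "log2")
  e2 <- module_eigenprotein(flipped, ids)
  expect_equal(unname(e2), unname(-e), tolerance = 1e-10)

  set.seed(41)
  sim <- simulate_reference_brain(n_modules = 4L, proteins_per_module = 25L,
                                  n_samples = 100L, kme_target = 0.8,
                                  n_grey = 10L, seed = 9)
  for (m in rownames(sim$truth$latent)) {
    members <- names(sim$ref$membership)[sim$ref$membership == m]
    e <- module_eigenprotein(sim$abundance, members)
    expect_gt(abs(cor(e, sim$truth$latent[m, ])), 0.95)
  }
  expect_error(module_eigenprotein(M, ids[1]), "fewer than 2")
})

test_that("eigenprotein explains more variance than random subsets", {
  sim <- simulate_reference_brain(n_modules = 3L, proteins_per_module = 20L,
                                  n_samples = 80L, kme_target = 0.7,
                                  n_grey = 150L, seed = 43)
  M <- sim$abundance
  var_explained <- function(ids) {
    X <- t(scale(t(M[ids, ])))
    sv <- svd(X)
    sv$d[1]^2 / sum(sv$d^2)
  }
  members <- names(sim$ref$membership)[sim$ref$membership == "M1"]
  ve_mod <- var_explained(members)
  set.seed(44)
  grey <- names(sim$ref$membership)[sim$ref$membership == "grey"]
  ve_rand <- replicate(100, var_explained(sample(grey, length(members))))
  expect_true(all(ve_mod > ve_rand))
})

test_that("kME assignment follows the inclusive 0.30 threshold rule", {
  set.seed(47)
  n <- 60
  e1 <- rnorm(n); e2 <- rnorm(n)
  eig <- rbind(M1 = (e1 - mean(e1)) / sd(e1), M2 = (e2 - mean(e2)) / sd(e2))
  colnames(eig) <- sprintf("s%02d", 1:n)
  mem <- setNames(c("M1", "M2"), c("P90001|X1", "P90002|X2"))
  ref <- network_reference(mem, eig)
  # protein identical to the M2 eigenprotein; plus a pure-noise protein
  vals <- rbind(eig["M2", ], rnorm(n))
  dimnames(vals) <- list(c("PA|AA", "PB|BB"), colnames(eig))
  out <- assign_to_modules(abundance_matrix(vals, "log2"), ref)
  expect_equal(out$assigned_module[1], "M2")
  expect_equal(out$kme_best[1], 1, tolerance = 1e-12)
  kme_all <- attr(out, "kme_all")
  expect_equal(dim(kme_all), c(2L, 2L))

  # boundary: kme exactly at / just under the threshold
  mk_target <- function(target) {
    repeat {
      cand <- target * eig["M1", ] + sqrt(1 - target^2) * rnorm(n)
      b <- bicor(cand, eig["M1", ])
      if (abs(b - target) < 0.002) return(list(x = cand, b = b))
    }
  }
  just_under <- mk_target(0.25)
  vals2 <- rbind(just_under$x)
  dimnames(vals2) <- list("PC|CC", colnames(eig))
  out2 <- assign_to_modules(abundance_matrix(vals2, "log2"), ref, kme_min = 0.30)
  expect_equal(out2$assigned_module, "grey")
  # a kME exactly at the threshold is assigned (inclusive rule)
  out3 <- assign_to_modules(abundance_matrix(vals2, "log2"), ref,
                            kme_min = out2$kme_best)
  expect_equal(out3$assigned_module, "M1")
})

test_that("assignment is invariant to per-protein affine rescaling", {
  sim <- simulate_reference_brain(n_modules = 5L, proteins_per_module = 10L,
                                  n_samples = 50L, kme_target = 0.7,
                                  n_grey = 20L, seed = 51)
  M <- sim$abundance
  out1 <- assign_to_modules(M, sim$ref)
  scaled <- M * rep(runif(nrow(M), 0.5, 3), ncol(M)) + rep(rnorm(nrow(M)), ncol(M))
  scaled <- abundance_matrix(matrix(scaled, nrow(M), dimnames = dimnames(M)), "log2")
  out2 <- assign_to_modules(scaled, sim$ref)
  expect_equal(out1$assigned_module, out2$assigned_module)
  expect_equal(out1$kme_best, out2$kme_best, tolerance = 1e-9)
})

test_that("planted network is recovered by reassignment", {
  sim <- simulate_reference_brain(n_modules = 10L, proteins_per_module = 25L,
                                  n_samples = 100L, kme_target = 0.6,
                                  n_grey = 60L, seed = 53)
  out <- assign_to_modules(sim$abundance, sim$ref)
  truth <- sim$truth$true_membership[out$protein_id]
  members <- truth != "grey"
  expect_gt(mean(out$assigned_module[members] == truth[members]), 0.9)
  expect_gt(mean(out$assigned_module[!members] == "grey"), 0.8)
})

test_that("module-trait bicor recovers a planted trait association", {
  sim <- simulate_reference_brain(n_modules = 6L, proteins_per_module = 10L,
                                  n_samples = 90L, kme_target = 0.7,
                                  n_grey = 10L, seed = 57,
                                  matrisome_module = "M3")
  mt <- module_trait_bicor(sim$ref$eigenproteins, sim$traits)
  expect_equal(dim(mt$r), c(6L, 3L))
  expect_gt(mt$r["M3", "CERAD"], 0.5)
  expect_lt(mt$p["M3", "CERAD"], 1e-6)
  expect_lt(mt$r["M3", "MMSE"], -0.4)
  others <- setdiff(rownames(mt$r), "M3")
  expect_lt(max(abs(mt$r[others, "CERAD"])), 0.4)
  # constant trait flagged missing
  traits2 <- sim$traits; traits2$CERAD <- 1
  mt2 <- module_trait_bicor(sim$ref$eigenproteins, traits2)
  expect_true(all(is.na(mt2$r[, "CERAD"])))
})

test_that("module-trait null correlations reject near the nominal rate", {
  set.seed(59)
  n <- 50
  eig <- matrix(rnorm(n), 1, dimnames = list("M1", sprintf("s%d", 1:n)))
  eig <- (eig - mean(eig)) / sd(eig)
  hits <- replicate(1000, {
    tr <- data.frame(sample_id = colnames(eig), x = rnorm(n))
    module_trait_bicor(eig, tr)$p[1, 1] < 0.05
  })
  expect_gt(mean(hits), 0.03)
  expect_lt(mean(hits), 0.08)
})

test_that("one-tailed FET matches hand-derived and enumerated values", {
  got <- fisher_exact_one_tailed(3, 4, 4, 8)
  expect_equal(got$p, 17 / 70, tolerance = 1e-12)
  expect_equal(got$z, 1.32287565553230, tolerance = 1e-10)
  expect_equal(fisher_exact_one_tailed(0, 4, 4, 8)$p, 1)
  degen <- fisher_exact_one_tailed(5, 5, 5, 5)
  expect_equal(degen$p, 1)
  expect_equal(degen$z, 0)
  expect_error(fisher_exact_one_tailed(5, 4, 4, 8), "margins")
})

test_that("module overlap FET flags the seeded module first", {
  sim <- simulate_reference_brain(n_modules = 6L, proteins_per_module = 15L,
                                  n_samples = 30L, kme_target = 0.6,
                                  n_grey = 40L, seed = 61)
  ref <- sim$ref
  background <- names(ref$membership)
  m2 <- names(ref$membership)[ref$membership == "M2"]
  out <- module_overlap_fet(fg_up = m2, fg_down = character(0), ref, background)
  up <- out[out$foreground == "up", ]
  expect_equal(up$set_id[which.min(up$p_one_tailed)], "M2")
  expect_true(all(up$p_one_tailed[up$set_id != "M2"] >= min(up$p_one_tailed)))
  # disjoint foreground: k = 0, p = 1
  m3 <- names(ref$membership)[ref$membership == "M3"]
  row_m3 <- out[out$foreground == "up" & out$set_id == "M3", ]
  expect_equal(row_m3$overlap_k, 0L)
  expect_equal(row_m3$p_one_tailed, 1)
  expect_error(module_overlap_fet(c(m2, "XX|YY"), character(0), ref, background),
               "subset")
})

test_that("cell-type FET matches markers case-insensitively and BH-adjusts", {
  sim <- simulate_reference_brain(n_modules = 4L, proteins_per_module = 20L,
                                  n_samples = 30L, kme_target = 0.6,
                                  n_grey = 60L, seed = 67)
  ref <- sim$ref
  background <- names(ref$membership)
  m1_syms <- gene_symbols(names(ref$membership)[ref$membership == "M1"])
  markers <- list(astro = tolower(m1_syms[1:16]),      # lower-case on purpose
                  micro = paste0("ZZZ", 1:10))         # disjoint from network
  out <- celltype_fet(ref, markers, background)
  astro_m1 <- out[out$set_id == "M1" & out$foreground == "astro", ]
  expect_lt(astro_m1$q_bh, 0.001)
  expect_equal(astro_m1$overlap_k, 16L)
  expect_true(all(out$p_one_tailed[out$foreground == "micro"] == 1))
  expect_error(celltype_fet(ref, list(a = character(0)), background), "non-empty")
  expect_error(celltype_fet(ref, markers, character(0)), "empty")
})
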