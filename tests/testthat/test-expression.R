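test_that("RPKM formula is exact and linear", {
  expect_equal(compute_rpkm(10, 1e6, 1000), 10)
  expect_equal(compute_rpkm(0, 5e6, 700), 0)
  expect_equal(compute_rpkm(50, 2e6, 500), 50)
  expect_error(compute_rpkm(10, 0, 1000), "N")
  expect_error(compute_rpkm(-1, 1e6, 1000), "non-negative")

  set.seed(3)
  for (i in 1:10) {
    C <- sample(1:1000, 1); N <- sample(1e5:1e7, 1); L <- sample(100:5000, 1)
    r <- compute_rpkm(C, N, L)
    expect_equal(compute_rpkm(2 * C, N, L), 2 * r)
    expect_equal(compute_rpkm(C, 2 * N, L), r / 2)
    expect_equal(compute_rpkm(C, N, 2 * L), r / 2)
  }
})

test_that("rpkm_table ranks by abundance and forms condition ratios", {
  counts <- data.frame(gene_id = c("g1", "g2"), length_bp = c(500L, 1000L),
                       winged = c(10L, 10L), wingless = c(20L, 10L))
  ct <- make_count_table(counts, c(winged = 1e6, wingless = 2e6))
  res <- rpkm_table(ct)
  w <- res$records[res$records$condition == "winged", ]
  expect_equal(w$rpkm[w$gene_id == "g1"], 2 * w$rpkm[w$gene_id == "g2"])
  expect_equal(w$gene_id[w$rank == 1L], "g1")
  # same L, C doubled with N doubled: ratio 1
  expect_equal(res$comparison$ratio[res$comparison$gene_id == "g1"], 1)

  zero <- make_count_table(
    data.frame(gene_id = "g", length_bp = 100L, a = 5L, b = 0L),
    c(a = 1e6, b = 1e6))
  expect_equal(rpkm_table(zero, "a", "b")$comparison$ratio, Inf)
})

test_that("simulated counts recover true RPKM within Poisson error", {
  n_genes <- 1000L
  set.seed(2024)
  true_rpkm <- setNames(10^runif(n_genes, 0.7, 3), sprintf("g%04d", 1:n_genes))
  L <- setNames(sample(500:2000, n_genes, replace = TRUE), names(true_rpkm))
  N <- c(winged = 1e6)
  ct <- sim_counts(true_rpkm, L, N, seed = 42L)
  res <- rpkm_table(ct)
  rec <- res$records
  lambda <- true_rpkm[rec$gene_id] * N[["winged"]] * L[rec$gene_id] / 1e9
  se_rpkm <- 1e9 * sqrt(lambda) / (N[["winged"]] * L[rec$gene_id])
  within <- abs(rec$rpkm - true_rpkm[rec$gene_id]) <= 3 * se_rpkm
  expect_gte(mean(within), 0.99)
})

test_that("standard-curve efficiency and the 90-110% window", {
  sc <- fit_standard_curve(c(0, -1, -2, -3), 20 + 3.3219 * c(0, 1, 2, 3))
  expect_equal(sc$slope, -3.3219, tolerance = 1e-6)
  expect_equal(sc$efficiency_percent, 100, tolerance = 0.01)
  expect_true(sc$passes)

  sc2 <- fit_standard_curve(c(0, -1, -2, -3), 20 + 3.6 * c(0, 1, 2, 3))
  expect_equal(sc2$efficiency_percent, 100 * (10^(1 / 3.6) - 1),
               tolerance = 1e-9)
  expect_equal(sc2$efficiency_percent, 89.57, tolerance = 0.01)
  expect_false(sc2$passes)

  expect_warning(pos <- fit_standard_curve(c(0, -1, -2), c(22, 21, 20)),
                 "slope")
  expect_false(pos$passes)
  expect_error(fit_standard_curve(c(0, 0, 0), c(1, 2, 3)), "distinct")
})

test_that("normalization cancels sample loading shifts exactly", {
  folds <- rbind(ref1 = c(s1 = 1, s2 = 1, s3 = 1),
                 ref2 = c(1, 1, 1),
                 tg = c(1, 2, 8))
  ctt <- sim_ct_table(folds, base_ct = c(ref1 = 18, ref2 = 21, tg = 25),
                      shifts = c(s1 = 0.7, s2 = -1.2, s3 = 2.5), seed = 5L)
  norm <- vandesompele_normalize(ctt, c("ref1", "ref2"), calibrator = "s1")
  tg <- norm[norm$gene_id == "tg", ]
  expect_equal(setNames(tg$fold, tg$sample_id), c(s1 = 1, s2 = 2, s3 = 8),
               tolerance = 1e-12)

  # all Cts identical across samples: everything normalizes to 1
  flat <- sim_ct_table(matrix(1, 3, 3, dimnames = list(c("ref1", "ref2", "tg"),
                                                       c("s1", "s2", "s3"))),
                       base_ct = c(ref1 = 20, ref2 = 20, tg = 20), seed = 6L)
  nf <- vandesompele_normalize(flat, c("ref1", "ref2"), calibrator = "s1")
  expect_true(all(abs(nf$norm - 1) < 1e-12))
  expect_true(all(abs(nf$fold - 1) < 1e-12))
})

test_that("a one-cycle Ct drop at amplification factor 2 doubles the fold", {
  folds <- rbind(ref1 = c(cal = 1, s = 1), ref2 = c(1, 1), tg = c(1, 2))
  ctt <- sim_ct_table(folds, base_ct = c(ref1 = 20, ref2 = 22, tg = 26),
                      seed = 8L)
  raw <- as.data.frame(ctt)
  d_ct <- mean(raw$ct[raw$gene_id == "tg" & raw$sample_id == "cal"]) -
    mean(raw$ct[raw$gene_id == "tg" & raw$sample_id == "s"])
  expect_equal(d_ct, 1)
  norm <- vandesompele_normalize(ctt, c("ref1", "ref2"), calibrator = "cal")
  expect_equal(norm$fold[norm$gene_id == "tg" & norm$sample_id == "s"], 2)
})

test_that("noisy planted folds are recovered within 10%", {
  folds <- rbind(ref1 = c(s1 = 1, s2 = 1, s3 = 1),
                 ref2 = c(1, 1, 1),
                 tg = c(1, 2, 8))
  ctt <- sim_ct_table(folds, base_ct = c(ref1 = 18, ref2 = 21, tg = 25),
                      shifts = c(s1 = 0, s2 = 0.4, s3 = -0.3),
                      noise_sd = 0.05, n_reps = 3L, seed = 12L)
  norm <- vandesompele_normalize(ctt, c("ref1", "ref2"), calibrator = "s1")
  tg <- norm[norm$gene_id == "tg", ]
  rel_err <- abs(setNames(tg$fold, tg$sample_id) - folds["tg", ]) / folds["tg", ]
  expect_lt(max(rel_err), 0.10)
})

test_that("normalization validates references and efficiencies", {
  folds <- rbind(ref1 = c(s1 = 1, s2 = 1), tg = c(1, 2))
  ctt <- sim_ct_table(folds, base_ct = c(ref1 = 20, tg = 24), seed = 9L)
  expect_error(vandesompele_normalize(ctt, "missing_ref"), "missing_ref")
  expect_error(vandesompele_normalize(ctt, "ref1",
                                      efficiencies = c(tg = -2)), "positive")
  expect_error(vandesompele_normalize(ctt, "ref1", calibrator = "nope"),
               "calibrator")
})

test_that("ANOVA F matches brute-force sums of squares on random data", {
  set.seed(31)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    n <- sample(3:6, 1)
    vals <- rnorm(k * n, mean = rep(runif(k, 0, 4), each = n))
    grp <- rep(paste0("g", 1:k), each = n)
    res <- anova_lsd(vals, grp)
    expect_equal(res$F, oracle_anova_F(vals, grp), tolerance = 1e-8)
  }
})

test_that("the hand-computed three-group example letters correctly", {
  vals <- c(1, 2, 3, 2, 3, 4, 21, 22, 23)
  grp <- rep(c("g1", "g2", "g3"), each = 3)
  res <- anova_lsd(vals, grp)
  expect_equal(res$mse, 1)
  expect_equal(res$F, 381) # SSB = 3*((2-9)^2+(3-9)^2+(22-9)^2) = 762, MSE = 1
  expect_equal(res$letters[["g1"]], res$letters[["g2"]])
  expect_false(res$letters[["g3"]] == res$letters[["g1"]])
})

test_that("two-group letter split agrees with a pooled t-test", {
  set.seed(17)
  for (i in 1:30) {
    a <- rnorm(4, 0, 1)
    b <- rnorm(4, sample(c(0, 0.5, 2, 4), 1), 1)
    res <- anova_lsd(c(a, b), rep(c("a", "b"), each = 4))
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(res$letters[["a"]] != res$letters[["b"]],
                 tt$p.value < 0.05)
  }
})

test_that("identical groups always share a letter; degenerate cases handled", {
  res <- anova_lsd(rep(1, 9), rep(c("a", "b", "c"), each = 3))
  expect_equal(res$F, 0)
  expect_true(all(res$letters == res$letters[[1]]))

  # zero within-group variance, unequal means
  res2 <- anova_lsd(rep(c(1, 2, 5), each = 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(res2$F, Inf)
  expect_equal(length(unique(res2$letters)), 3L)

  expect_error(anova_lsd(c(1, 2, 3), c("a", "a", "b")), "fewer than 2")
  expect_error(anova_lsd(c(1, 2), c("a", "a")), "at least 2 groups")
})
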