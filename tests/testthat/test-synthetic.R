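lib <- motif_library()

test_that("plant_motif places anchors exactly and is seed-deterministic", {
  pl <- plant_motif(lib$OBP_CLASSIC, c(22L, 3L, 36L, 8L, 8L),
                    flanks = c(1L, 0L), seed = 2L)
  expect_equal(nchar(pl$protein), 1L + 6L + 22L + 3L + 36L + 8L + 8L)
  chars <- strsplit(pl$protein, "")[[1]]
  expect_true(all(chars[pl$positions] == "C"))
  expect_equal(sum(chars == "C"), 6L) # fill excludes anchor letters
  hits <- scan_motif(pl$protein, lib$OBP_CLASSIC)
  expect_equal(hits, list(pl$positions))

  expect_error(plant_motif(lib$OBP_CLASSIC, c(21L, 3L, 36L, 8L, 8L)),
               "outside range")
  expect_identical(plant_motif(lib$CSP_RESULTS, c(5L, 18L, 2L), seed = 9L),
                   plant_motif(lib$CSP_RESULTS, c(5L, 18L, 2L), seed = 9L))
})

test_that("planted motifs are recovered across their full gap ranges", {
  set.seed(55)
  for (m in lib) {
    vecs <- list(m$gap_min, m$gap_max, sample_gaps(m))
    for (gaps in vecs) {
      pl <- plant_motif(m, as.integer(gaps),
                        flanks = c(3L, max(3L, m$min_tail)))
      hits <- scan_motif(pl$protein, m)
      expect_true(any(vapply(hits, identical, TRUE, pl$positions)),
                  info = m$name)
    }
  }
})

test_that("perturbing a gap out of range abolishes the match, and back", {
  pl <- plant_motif(lib$OBP_GENERAL, c(39L, 3L, 30L, 8L, 8L), seed = 6L)
  # widen C1-C2 from 39 to 49: outside the general range
  wide <- perturb_gap(pl$protein, pl$positions, 1L, 10L,
                      spec = lib$OBP_GENERAL, seed = 7L)
  expect_length(scan_motif(wide$protein, lib$OBP_GENERAL), 0L)
  restored <- perturb_gap(wide$protein, wide$positions, 1L, -10L)
  expect_length(scan_motif(restored$protein, lib$OBP_GENERAL), 1L)

  same <- perturb_gap(pl$protein, pl$positions, 1L, 0L)
  expect_identical(same$protein, pl$protein)
  expect_error(perturb_gap(pl$protein, pl$positions, 2L, -4L), "negative")
})

test_that("every built-in motif rejects each out-of-range gap perturbation", {
  set.seed(66)
  for (m in lib) {
    pl <- plant_motif(m, m$gap_min, flanks = c(3L, max(3L, m$min_tail)))
    for (g in seq_along(m$gap_min)) {
      over <- perturb_gap(pl$protein, pl$positions, g,
                          m$gap_max[g] - m$gap_min[g] + 1L, spec = m)
      expect_equal(length(scan_motif(over$protein, m)), 0L,
                   info = paste(m$name, "gap", g))
      if (m$gap_min[g] > 0L) {
        under <- perturb_gap(pl$protein, pl$positions, g, -1L, spec = m)
        expect_equal(length(scan_motif(under$protein, m)), 0L,
                     info = paste(m$name, "gap", g, "under"))
      }
    }
  }
})

test_that("transcript generation is seed-stable and labels truth", {
  plans <- list(list(id = "a", spec = "CSP_RESULTS", gaps = c(5L, 18L, 2L),
                     flanks = c(30L, 30L)))
  g1 <- gen_transcript_set(plans, n_negatives = 2L, seed = 33L)
  g2 <- gen_transcript_set(plans, n_negatives = 2L, seed = 33L)
  expect_identical(g1, g2)
  expect_equal(g1$truth$family, c("CSP_RESULTS", "NONE", "NONE"))
  expect_equal(nrow(g1$transcripts), 3L)
})

test_that("count simulation matches its design", {
  ct <- sim_counts(c(g1 = 10, g2 = 0), c(g1 = 1000, g2 = 800),
                   c(winged = 1e6, wingless = 2e6), seed = 4L)
  expect_s3_class(ct, "count_table")
  expect_equal(ct$counts$wingless[2], 0) # rpkm 0 gives count 0 always
  expect_identical(ct, sim_counts(c(g1 = 10, g2 = 0), c(g1 = 1000, g2 = 800),
                                  c(winged = 1e6, wingless = 2e6), seed = 4L))
})

test_that("noiseless Ct tables encode folds as exact cycle differences", {
  folds <- rbind(ref = c(a = 1, b = 1), tg = c(1, 2))
  ctt <- sim_ct_table(folds, base_ct = c(ref = 20, tg = 24), seed = 3L)
  raw <- as.data.frame(ctt)
  cts <- tapply(raw$ct, list(raw$gene_id, raw$sample_id), mean)
  expect_equal(cts["tg", "a"] - cts["tg", "b"], 1) # fold 2, factor 2
  expect_equal(cts["ref", "a"], cts["ref", "b"])
})

test_that("tree simulation is deterministic and respects branch lengths", {
  s1 <- sim_alignment_on_tree("((A:0.1,B:0.1):0.2,(C:0.1,D:0.1):0.2);",
                              root_length = 80L, seed = 5L)
  s2 <- sim_alignment_on_tree("((A:0.1,B:0.1):0.2,(C:0.1,D:0.1):0.2);",
                              root_length = 80L, seed = 5L)
  expect_identical(s1$alignment, s2$alignment)

  zero <- sim_alignment_on_tree("((A:0,B:0):0,(C:0,D:0):0);",
                                root_length = 60L, seed = 6L)
  expect_length(unique(zero$alignment), 1L)
})
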