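lib <- motif_library()

test_that("motif parser handles gap ranges, fixed gaps and adjacency", {
  m <- parse_motif("C-x(15,39)-C-x(3)-C-x(21,44)-C-x(7,12)-C-x(8)-C")
  expect_equal(m$anchors, rep("C", 6))
  expect_equal(m$gap_min, c(15L, 3L, 21L, 7L, 8L))
  expect_equal(m$gap_max, c(39L, 3L, 44L, 12L, 8L))

  m2 <- parse_motif("C-x(5,6)-C-x(18,19)-C-x(2)-C")
  expect_equal(length(m2$anchors), 4L)
  expect_equal(m2$gap_min, c(5L, 18L, 2L))

  adj <- parse_motif("C-P-x(9,10)-C")
  expect_equal(adj$gap_min, c(0L, 9L))

  tail <- parse_motif("C-x(2)-C-x(9,10)")
  expect_equal(tail$min_tail, 9L)

  expect_error(parse_motif("C-x(3,2)-C"), "min > max")
  expect_error(parse_motif("C-y(3)-C"), "malformed")
  expect_error(parse_motif("C"), "at least 2 anchors")
})

test_that("scanner finds planted assignments and rejects out-of-range spacings", {
  # planted at the classic lower bounds 22,3,36,8,8
  p <- paste0("M", "C", strrep("A", 22), "C", strrep("A", 3), "C",
              strrep("A", 36), "C", strrep("A", 8), "C", strrep("A", 8), "C")
  hits <- scan_motif(p, lib$OBP_CLASSIC)
  expect_length(hits, 1L)
  expect_equal(hits[[1]], c(2L, 25L, 29L, 66L, 75L, 84L))

  # a 49-residue C1-C2 spacing exceeds the general OBP maximum of 39
  p49 <- plant_motif(parse_motif("C-x(49)-C-x(3)-C-x(30)-C-x(8)-C-x(8)-C"),
                     gaps = c(49L, 3L, 30L, 8L, 8L), seed = 1L)
  expect_length(scan_motif(p49$protein, lib$OBP_GENERAL), 0L)

  set.seed(9)
  for (i in 1:20) {
    expect_length(scan_motif(random_protein(60, setdiff(LETTERS, "C")),
                             lib$OBP_GENERAL), 0L)
  }
})

test_that("scanner agrees exactly with the exhaustive oracle", {
  set.seed(101)
  specs <- lib[c("OBP_GENERAL", "OBP_CLASSIC", "CSP_METHODS", "CSP_RESULTS")]
  # random proteins (C-enriched so anchors occur)
  alphabet <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], rep("C", 4))
  for (i in 1:120) {
    p <- random_protein(sample(40:120, 1), alphabet)
    for (m in specs) {
      expect_equal(scan_motif(p, m), oracle_scan(p, m), info = m$name)
    }
  }
  # planted proteins, anchors allowed in gaps (stress mode)
  for (i in 1:60) {
    m <- specs[[sample.int(length(specs), 1)]]
    gaps <- sample_gaps(m)
    pl <- plant_motif(m, gaps, flanks = c(sample(0:5, 1), sample(0:5, 1)),
                      exclude_anchors = FALSE)
    got <- scan_motif(pl$protein, m)
    expect_equal(got, oracle_scan(pl$protein, m), info = m$name)
    expect_true(any(vapply(got, identical, TRUE, pl$positions)))
  }
})

test_that("widening a gap range never loses matches", {
  set.seed(77)
  alphabet <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], rep("C", 5))
  for (i in 1:30) {
    p <- random_protein(90, alphabet)
    base <- lib$CSP_RESULTS
    n0 <- length(scan_motif(p, base))
    wide <- base
    g <- sample(seq_along(wide$gap_min), 1)
    wide$gap_min[g] <- max(0L, wide$gap_min[g] - sample(1:3, 1))
    wide$gap_max[g] <- wide$gap_max[g] + sample(1:3, 1)
    expect_gte(length(scan_motif(p, wide)), n0)
  }
})

test_that("every reported match satisfies the motif definition", {
  set.seed(13)
  alphabet <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], rep("C", 6))
  for (i in 1:40) {
    p <- random_protein(100, alphabet)
    chars <- strsplit(p, "")[[1]]
    for (m in lib[c("OBP_GENERAL", "CSP_RESULTS")]) {
      for (hit in scan_motif(p, m)) {
        expect_true(all(diff(hit) > 0))
        expect_equal(chars[hit], m$anchors)
        gaps <- diff(hit) - 1L
        expect_true(all(gaps >= m$gap_min & gaps <= m$gap_max))
      }
    }
  }
})

test_that("classification applies independent flags and fixed precedence", {
  # classic-only: C3-C4 spacing 45 is inside classic (36-46), outside
  # general (21-44)
  spec45 <- parse_motif("C-x(25)-C-x(3)-C-x(45)-C-x(9)-C-x(8)-C")
  p45 <- plant_motif(spec45, c(25L, 3L, 45L, 9L, 8L), seed = 3L)
  call45 <- classify_protein(p45$protein)
  expect_equal(call45$flags, "OBP_CLASSIC")
  expect_equal(call45$primary_family, "OBP_CLASSIC")
  expect_length(oracle_scan(p45$protein, lib$OBP_GENERAL), 0L)

  # overlap region: matches both general and classic, classic takes
  # precedence
  both <- plant_motif(lib$OBP_CLASSIC, c(25L, 3L, 40L, 10L, 8L), seed = 4L)
  callb <- classify_protein(both$protein)
  expect_setequal(callb$flags, c("OBP_GENERAL", "OBP_CLASSIC"))
  expect_equal(callb$primary_family, "OBP_CLASSIC")

  none <- classify_protein(strrep("A", 100))
  expect_equal(none$primary_family, "NONE")
  expect_length(none$flags, 0L)

  expect_error(classify_protein("AAAA", motifs = list()), "empty")
})

test_that("mine_candidates recovers the planted truth table", {
  plans <- list(
    list(id = "obp1", spec = "OBP_CLASSIC", gaps = c(25L, 3L, 40L, 10L, 8L)),
    list(id = "obp2", spec = "OBP_GENERAL", gaps = c(16L, 3L, 22L, 7L, 8L),
         flanks = c(20L, 20L)),
    list(id = "obp3", spec = "OBP_PLUSC",
         gaps = c(25L, 3L, 42L, 20L, 9L, 8L, 0L, 9L), flanks = c(5L, 12L)),
    list(id = "csp1", spec = "CSP_RESULTS", gaps = c(5L, 18L, 2L),
         flanks = c(30L, 30L)),
    list(id = "csp2", spec = "CSP_RESULTS", gaps = c(6L, 19L, 2L),
         flanks = c(30L, 30L)))
  gen <- gen_transcript_set(plans, n_negatives = 5L, seed = 21L)
  cand <- mine_candidates(gen$transcripts)
  expect_equal(sort(cand$transcript_id),
               sort(gen$truth$id[gen$truth$family != "NONE"]))
  fam <- setNames(cand$primary_family, cand$transcript_id)
  expect_equal(unname(fam[c("csp1", "csp2")]), c("CSP", "CSP"))
  expect_equal(unname(fam[["obp3"]]), "OBP_PLUSC")
  expect_true(fam[["obp1"]] %in% c("OBP_CLASSIC"))

  expect_equal(nrow(mine_candidates(gen$transcripts[0, ])), 0L)
})
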