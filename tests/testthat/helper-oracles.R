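# Independent oracles used across the suite. These deliberately share no
# code with the implementation they check.

# Exhaustive motif scan: enumerate every strictly increasing assignment of
# candidate anchor positions, then check each gap range and the tail.
oracle_scan <- function(protein, motif) {
  chars <- strsplit(protein, "")[[1]]
  n <- length(chars)
  k <- length(motif$anchors)
  cand <- lapply(motif$anchors, function(a) which(chars == a))
  out <- list()
  rec <- function(level, prev, acc) {
    if (level > k) {
      gaps <- diff(acc) - 1L
      if (all(gaps >= motif$gap_min & gaps <= motif$gap_max) &&
          n - acc[k] >= motif$min_tail) {
        out[[length(out) + 1L]] <<- acc
      }
      return()
    }
    for (p in cand[[level]]) {
      if (p > prev) rec(level + 1L, p, c(acc, p))
    }
  }
  rec(1L, 0L, integer())
  out
}

# Enumerate every global alignment of two short sequences and return the
# maximal affine-gap score together with the identities of all optimal
# alignments.
oracle_align <- function(a, b, match = 1, mismatch = 0,
                         gap_open = 10, gap_extend = 0.2) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  alns <- list()
  rec <- function(i, j, ra, rb) {
    if (i > length(ca) && j > length(cb)) {
      alns[[length(alns) + 1L]] <<- c(ra, rb)
      return()
    }
    if (i <= length(ca) && j <= length(cb)) {
      rec(i + 1L, j + 1L, paste0(ra, ca[i]), paste0(rb, cb[j]))
    }
    if (i <= length(ca)) rec(i + 1L, j, paste0(ra, ca[i]), paste0(rb, "-"))
    if (j <= length(cb)) rec(i, j + 1L, paste0(ra, "-"), paste0(rb, cb[j]))
  }
  rec(1L, 1L, "", "")
  score_one <- function(x, y) {
    cx <- strsplit(x, "")[[1]]
    cy <- strsplit(y, "")[[1]]
    s <- 0
    for (row in list(cx, cy)) {
      r <- rle(row == "-")
      s <- s - sum(ifelse(r$values, gap_open + gap_extend * r$lengths, 0))
    }
    both <- cx != "-" & cy != "-"
    s + sum(ifelse(cx[both] == cy[both], match, mismatch))
  }
  scores <- vapply(alns, function(p) score_one(p[1], p[2]), 0)
  best <- max(scores)
  opt <- alns[abs(scores - best) < 1e-9]
  ids <- vapply(opt, function(p) {
    cx <- strsplit(p[1], "")[[1]]
    cy <- strsplit(p[2], "")[[1]]
    100 * sum(cx == cy & cx != "-") / length(cx)
  }, 0)
  list(score = best, identities = ids)
}

# Brute-force one-way ANOVA F from sums of squares.
oracle_anova_F <- function(values, groups) {
  groups <- factor(groups)
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  n <- table(groups)
  ssb <- sum(n * (means - gm)^2)
  ssw <- sum((values - means[groups])^2)
  dfb <- nlevels(groups) - 1
  dfw <- length(values) - nlevels(groups)
  (ssb / dfb) / (ssw / dfw)
}

# Random additive distance matrix from a random tree with known topology.
random_additive <- function(ntaxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(ntaxa, br = function(n) stats::runif(n, 0.1, 1))
  tr$tip.label <- sort(tr$tip.label)[sample.int(ntaxa)]
  d <- as.matrix(ape::cophenetic.phylo(tr))
  ord <- sort(rownames(d))
  list(tree = tr, d = d[ord, ord])
}

# Canonical unrooted bipartition keys of a phylo, via ape.
oracle_bipartitions <- function(phy) {
  labels <- phy$tip.label
  anchor <- min(labels)
  ntip <- length(labels)
  parts <- ape::prop.part(phy)
  keys <- character()
  for (node in unique(phy$edge[, 1])) {
    if (node == ntip + 1) next
    tips <- labels[parts[[node - ntip]]]
    if (length(tips) <= 1 || length(tips) >= ntip - 1) next
    side <- if (anchor %in% tips) setdiff(labels, tips) else tips
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  sort(unique(keys))
}

random_protein <- function(len, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# one uniform draw per gap range (safe for degenerate single-value ranges)
sample_gaps <- function(m) {
  as.integer(mapply(function(a, b) a + sample.int(b - a + 1L, 1L) - 1L,
                    m$gap_min, m$gap_max))
}
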