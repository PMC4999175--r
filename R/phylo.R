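#' p-distance matrix from an aligned protein set
#'
#' For each pair, the proportion of differing columns among columns where
#' neither sequence has a gap. p-distance is not guaranteed metric; that is
#' acceptable for neighbour-joining input.
#'
#' @param aligned Named character vector of equal-length gapped sequences.
#' @return Symmetric numeric matrix with zero diagonal, labelled by names.
#' @export
p_distance_matrix <- function(aligned) {
  n <- length(aligned)
  if (n < 2L) stop("need at least 2 sequences")
  labels <- names(aligned)
  if (is.null(labels) || anyDuplicated(labels)) stop("unique names required")
  lens <- nchar(aligned)
  if (length(unique(lens)) != 1L) stop("aligned sequences differ in length")
  chars <- lapply(aligned, function(s) strsplit(s, "")[[1]])
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      a <- chars[[i]]
      b <- chars[[j]]
      comp <- a != "-" & b != "-"
      nc <- sum(comp)
      if (nc == 0L) {
        stop("no comparable columns between ", labels[i], " and ", labels[j])
      }
      d[i, j] <- d[j, i] <- sum(a[comp] != b[comp]) / nc
    }
  }
  d
}

# Smallest leaf label below each working node, used for deterministic
# tie-breaking during agglomeration.
.pair_key <- function(r1, r2) {
  paste(sort(c(r1, r2)), collapse = "\r")
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: at each step the pair minimising
#' `Q(i,j) = (r - 2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)` is joined, with
#' the standard branch-length formulas. Negative branch lengths are clamped
#' to zero. Ties in Q are broken by the lexicographically smallest pair of
#' subtree representative labels, so the output is deterministic. The result
#' is unrooted, represented with a trifurcating root.
#'
#' @param d Symmetric distance matrix with labelled rows/columns and zero
#'   diagonal (at least 3 taxa).
#' @return An [ape::read.tree] `phylo` object.
#' @export
nj_build <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("d must be a square matrix")
  labels <- rownames(d)
  if (is.null(labels)) stop("d must have row labels")
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")
  if (any(d < 0)) stop("negative distances not allowed")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix must be symmetric")

  # working nodes hold a newick fragment and a representative label
  frag <- labels
  rep_lab <- labels
  D <- d
  fmt <- function(x) sprintf("%.12g", max(x, 0))
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1L, function(ij) .pair_key(rep_lab[ij[1]], rep_lab[ij[2]]))
    pick <- cand[order(keys)[1L], ]
    i <- pick[1L]
    j <- pick[2L]
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    new_frag <- paste0("(", frag[i], ":", fmt(vi), ",",
                       frag[j], ":", fmt(vj), ")")
    new_rep <- min(rep_lab[i], rep_lab[j])
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    D <- D2
    frag <- c(frag[keep], new_frag)
    rep_lab <- c(rep_lab[keep], new_rep)
  }
  # final three-way join (three-point formulas)
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  ord <- order(rep_lab)
  lens <- c(la, lb, lc)[ord]
  fr <- frag[ord]
  nwk <- paste0("(", fr[1], ":", fmt(lens[1]), ",",
                fr[2], ":", fmt(lens[2]), ",",
                fr[3], ":", fmt(lens[3]), ");")
  ape::read.tree(text = nwk)
}

# Canonical bipartition keys of the internal edges of an unrooted phylo.
# Each non-root internal node defines the split (tips below it | rest);
# the side not containing the alphabetically first label is the key.
.bipartitions <- function(phy) {
  labels <- phy$tip.label
  anchor <- min(labels)
  parts <- ape::prop.part(phy)
  ntip <- length(labels)
  keys <- character()
  root <- ntip + 1L
  internal <- setdiff(unique(phy$edge[, 1L]), integer(0))
  for (node in internal) {
    if (node == root) next
    tips <- labels[parts[[node - ntip]]]
    if (length(tips) <= 1L || length(tips) >= ntip - 1L) next
    side <- if (anchor %in% tips) setdiff(labels, tips) else tips
    keys <- c(keys, paste(sort(side), collapse = "\r"))
  }
  unique(keys)
}

#' Bootstrap supports for a neighbour-joining protein tree
#'
#' Alignment columns are resampled with replacement `n_reps` times; each
#' replicate yields a p-distance matrix and an NJ tree. The support of each
#' internal edge of the tree built from the original alignment is the
#' percentage of (successful) replicates whose tree contains the same leaf
#' bipartition. Replicates in which some pair has no comparable columns are
#' skipped with a warning and excluded from the denominator.
#'
#' @param aligned Named character vector of equal-length gapped sequences.
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed controlling column resampling.
#' @return A `phylo` tree with integer percent supports in `node.label`
#'   (empty for the root) and attribute `n_skipped`.
#' @export
bootstrap_supports <- function(aligned, n_reps = 1000L, seed = 1L) {
  stopifnot(n_reps >= 1L)
  tree <- nj_build(p_distance_matrix(aligned))
  orig_keys <- .bipartitions(tree)
  counts <- stats::setNames(numeric(length(orig_keys)), orig_keys)
  chars <- do.call(rbind, lapply(aligned, function(s) strsplit(s, "")[[1]]))
  L <- ncol(chars)
  n_skipped <- 0L
  with_seed(seed, {
    for (b in seq_len(n_reps)) {
      cols <- sample.int(L, L, replace = TRUE)
      rep_aln <- apply(chars[, cols, drop = FALSE], 1L, paste, collapse = "")
      names(rep_aln) <- names(aligned)
      keys <- tryCatch(.bipartitions(nj_build(p_distance_matrix(rep_aln))),
                       error = function(e) NULL)
      if (is.null(keys)) {
        n_skipped <- n_skipped + 1L
        next
      }
      hit <- orig_keys %in% keys
      counts[hit] <- counts[hit] + 1
    }
  })
  if (n_skipped > 0L) {
    warning(n_skipped, " bootstrap replicate(s) skipped (no comparable columns)")
  }
  used <- n_reps - n_skipped
  supports <- if (used > 0L) round(100 * counts / used) else counts * NA
  # attach supports as node labels
  labels <- tree$tip.label
  anchor <- min(labels)
  ntip <- length(labels)
  parts <- ape::prop.part(tree)
  node_lab <- character(tree$Nnode)
  for (node in seq.int(ntip + 1L, ntip + tree$Nnode)) {
    if (node == ntip + 1L) next # root of the trifurcating representation
    tips <- labels[parts[[node - ntip]]]
    side <- if (anchor %in% tips) setdiff(labels, tips) else tips
    key <- paste(sort(side), collapse = "\r")
    if (key %in% names(supports)) {
      node_lab[node - ntip] <- as.character(as.integer(supports[[key]]))
    }
  }
  tree$node.label <- node_lab
  attr(tree, "n_skipped") <- n_skipped
  tree
}

.newick_quote <- function(lab) {
  if (grepl("[][ ()':;,]", lab)) {
    paste0("'", gsub("'", "''", lab), "'")
  } else {
    lab
  }
}

#' Write a tree as newick
#'
#' Branch lengths are written with 6 significant digits; internal node
#' labels (e.g. integer bootstrap supports) are preserved; labels containing
#' newick metacharacters are single-quoted per the standard.
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  node_lab <- tree$node.label
  fmt_node <- function(node, edge_idx) {
    len <- if (is.null(edge_idx)) NULL else tree$edge.length[edge_idx]
    body <- if (node <= ntip) {
      .newick_quote(tree$tip.label[node])
    } else {
      ch <- kids[[as.character(node)]]
      inner <- vapply(ch, function(e) fmt_node(tree$edge[e, 2L], e), "")
      lab <- if (!is.null(node_lab)) node_lab[node - ntip] else ""
      if (is.na(lab)) lab <- ""
      paste0("(", paste(inner, collapse = ","), ")",
             if (nzchar(lab)) .newick_quote(lab) else "")
    }
    if (is.null(len) || is.na(len)) body else paste0(body, ":", sprintf("%.6g", len))
  }
  nwk <- paste0(fmt_node(ntip + 1L, NULL), ";")
  writeLines(nwk, path)
  invisible(path)
}
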