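#' Global pairwise alignment with affine gap penalties
#'
#' Needleman-Wunsch/Gotoh dynamic programming, end-to-end, with gap cost
#' `gap_open + k * gap_extend` for a gap of `k` residues. Defaults mirror
#' classic progressive-alignment penalties (opening 10, extension 0.2) with
#' an identity substitution scheme (match +1, mismatch 0).
#'
#' @param a,b Non-empty sequences (strings).
#' @param match,mismatch Substitution scores.
#' @param gap_open,gap_extend Affine gap penalties (positive values are
#'   costs).
#' @return List with `aligned_a`, `aligned_b` (gapped strings of equal
#'   length) and `score`.
#' @export
align_global <- function(a, b, match = 1, mismatch = 0,
                         gap_open = 10, gap_extend = 0.2) {
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty sequence")
  .align_global_cpp(a, b, match, mismatch, gap_open, gap_extend)
}

#' Percent identity of two proteins under global alignment
#'
#' Identity is the number of identical aligned residue pairs over the full
#' alignment length, gap columns included in the denominator.
#'
#' @inheritParams align_global
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b, match = 1, mismatch = 0,
                              gap_open = 10, gap_extend = 0.2) {
  aln <- align_global(a, b, match, mismatch, gap_open, gap_extend)
  ca <- strsplit(aln$aligned_a, "")[[1]]
  cb <- strsplit(aln$aligned_b, "")[[1]]
  100 * sum(ca == cb & ca != "-") / length(ca)
}

#' Pairwise percent-identity matrix over a protein set
#'
#' @param proteins Named character vector of protein sequences (names are
#'   unique labels).
#' @param ... Alignment parameters passed to [pairwise_identity()].
#' @return List with `percent` (labelled symmetric matrix, diagonal 100) and
#'   `range` (`c(min, max)` over off-diagonal pairs).
#' @export
identity_matrix <- function(proteins, ...) {
  if (length(proteins) < 2L) stop("need at least 2 proteins")
  labels <- names(proteins)
  if (is.null(labels) || anyDuplicated(labels)) {
    stop("proteins must carry unique names")
  }
  n <- length(proteins)
  mat <- matrix(100, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      pid <- pairwise_identity(proteins[[i]], proteins[[j]], ...)
      mat[i, j] <- pid
      mat[j, i] <- pid
    }
  }
  off <- mat[row(mat) != col(mat)]
  list(percent = mat, range = c(min = min(off), max = max(off)))
}

#' Center-star multiple alignment
#'
#' A guide multiple alignment for distance-based tree building when no
#' externally produced alignment is available: the center sequence (maximal
#' summed pairwise identity to all others) is aligned pairwise to every
#' other sequence and the pairwise alignments are merged under the
#' "once a gap, always a gap" rule.
#'
#' @param proteins Named character vector of protein sequences.
#' @param ... Alignment parameters passed to [align_global()].
#' @return Named character vector of equal-length gapped sequences.
#' @export
center_star_align <- function(proteins, ...) {
  n <- length(proteins)
  if (n < 2L) stop("need at least 2 sequences")
  labels <- names(proteins)
  if (is.null(labels) || anyDuplicated(labels)) stop("unique names required")
  if (n == 2L) {
    aln <- align_global(proteins[[1L]], proteins[[2L]], ...)
    out <- c(aln$aligned_a, aln$aligned_b)
    names(out) <- labels
    return(out)
  }
  idsum <- numeric(n)
  pairs <- vector("list", n)
  for (i in seq_len(n)) pairs[[i]] <- vector("list", n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      aln <- align_global(proteins[[i]], proteins[[j]], ...)
      ca <- strsplit(aln$aligned_a, "")[[1]]
      cb <- strsplit(aln$aligned_b, "")[[1]]
      pid <- 100 * sum(ca == cb & ca != "-") / length(ca)
      idsum[i] <- idsum[i] + pid
      idsum[j] <- idsum[j] + pid
      pairs[[i]][[j]] <- aln
    }
  }
  center <- which.max(idsum)
  master_center <- strsplit(proteins[[center]], "")[[1]]
  rows <- list()
  rows[[labels[center]]] <- master_center
  for (o in setdiff(seq_len(n), center)) {
    aln <- if (center < o) pairs[[center]][[o]] else {
      a <- pairs[[o]][[center]]
      list(aligned_a = a$aligned_b, aligned_b = a$aligned_a)
    }
    c_new <- strsplit(aln$aligned_a, "")[[1]] # center, possibly gapped
    s_new <- strsplit(aln$aligned_b, "")[[1]]
    i <- 1L
    j <- 1L
    len_m <- length(master_center)
    len_p <- length(c_new)
    m_cols <- integer() # column source in master (0 = new gap column)
    p_cols <- integer() # column source in pairwise alignment (0 = gap)
    while (i <= len_m || j <= len_p) {
      mi <- if (i <= len_m) master_center[i] else NA_character_
      pj <- if (j <= len_p) c_new[j] else NA_character_
      if (!is.na(mi) && !is.na(pj) && mi == pj) { # same center residue/gap
        m_cols <- c(m_cols, i); p_cols <- c(p_cols, j); i <- i + 1L; j <- j + 1L
      } else if (!is.na(mi) && mi == "-") { # master-only gap column
        m_cols <- c(m_cols, i); p_cols <- c(p_cols, 0L); i <- i + 1L
      } else { # insertion in the new sequence
        m_cols <- c(m_cols, 0L); p_cols <- c(p_cols, j); j <- j + 1L
      }
    }
    for (lab in names(rows)) {
      old <- rows[[lab]]
      rows[[lab]] <- ifelse(m_cols == 0L, "-", old[pmax(m_cols, 1L)])
    }
    master_center <- rows[[labels[center]]]
    rows[[labels[o]]] <- ifelse(p_cols == 0L, "-", s_new[pmax(p_cols, 1L)])
  }
  out <- vapply(rows, paste, "", collapse = "")
  out[labels] # original input order
}
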