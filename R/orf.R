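#' @useDynLib chemomine, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Translate a nucleotide sequence in a given frame
#'
#' Successive codons from `offset` are translated with the standard genetic
#' code; a trailing partial codon is dropped. Stop codons are rendered `*`;
#' any codon containing `N` is rendered `X`.
#'
#' @param nt_seq Nucleotide string over `{A,C,G,T,N}`.
#' @param offset Frame offset, 0, 1 or 2.
#' @return Amino-acid string (possibly empty).
#' @export
translate_nt <- function(nt_seq, offset = 0L) {
  stopifnot(length(nt_seq) == 1L, offset %in% 0:2)
  if (grepl("[^ACGTN]", nt_seq)) {
    stop("sequence contains characters outside {A,C,G,T,N}")
  }
  n <- nchar(nt_seq)
  if (n - offset < 3L) return("")
  starts <- seq.int(offset + 1L, by = 3L, length.out = (n - offset) %/% 3L)
  codons <- substring(nt_seq, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Reverse-complement a nucleotide sequence
#'
#' @param nt_seq Nucleotide string over `{A,C,G,T,N}`.
#' @return The reverse complement.
#' @export
reverse_complement <- function(nt_seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt_seq)))
}

# ORFs within one frame of one strand. Returns rows with coordinates local
# to the given sequence (1-based inclusive); caller maps to forward strand.
.frame_orfs <- function(seq, offset) {
  aa_full <- translate_nt(seq, offset)
  nc <- nchar(aa_full)
  if (nc == 0L) {
    return(NULL)
  }
  aa_vec <- strsplit(aa_full, "")[[1]]
  starts_nt <- seq.int(offset + 1L, by = 3L, length.out = nc)
  codons <- substring(seq, starts_nt, starts_nt + 2L)
  stop_idx <- which(aa_vec == "*")
  atg_idx <- which(codons == "ATG")

  orf <- function(from, to, has_start, has_stop) {
    # codon indices from..to cover the coding region incl. stop when present
    aa_to <- if (has_stop) to - 1L else to
    aa <- if (aa_to >= from) paste(aa_vec[from:aa_to], collapse = "") else ""
    list(start = starts_nt[from], end = starts_nt[to] + 2L,
         has_start = has_start, has_stop = has_stop, aa_seq = aa)
  }

  out <- list()
  for (a in atg_idx) {
    s <- stop_idx[stop_idx >= a]
    if (length(s) > 0L) {
      out[[length(out) + 1L]] <- orf(a, s[1L], TRUE, TRUE)
    } else {
      out[[length(out) + 1L]] <- orf(a, nc, TRUE, FALSE)
    }
  }
  # frame-initial segment running into a stop, when it does not begin at ATG
  if (length(stop_idx) > 0L && (length(atg_idx) == 0L || atg_idx[1L] != 1L)) {
    out[[length(out) + 1L]] <- orf(1L, stop_idx[1L], FALSE, TRUE)
  }
  out
}

#' Find open reading frames on both strands of a transcript
#'
#' An ORF runs from an `ATG` to the next in-frame stop codon (complete), or
#' to the end of the sequence (`has_stop = FALSE`); additionally the
#' frame-initial segment that reaches a stop without beginning at an `ATG`
#' is reported with `has_start = FALSE`, to accommodate 5'-truncated
#' transcripts. Coordinates are 1-based inclusive on the forward strand.
#'
#' @param seq Nucleotide string.
#' @param min_aa Minimum protein length to report.
#' @param id Transcript id carried into the result.
#' @return Data frame with columns `transcript_id`, `strand`, `frame`,
#'   `start`, `end`, `has_start`, `has_stop`, `aa_seq`, `length_aa`.
#' @export
find_orfs <- function(seq, min_aa = 80L, id = NA_character_) {
  stopifnot(min_aa >= 1L)
  empty <- data.frame(transcript_id = character(), strand = character(),
                      frame = integer(), start = integer(), end = integer(),
                      has_start = logical(), has_stop = logical(),
                      aa_seq = character(), length_aa = integer(),
                      stringsAsFactors = FALSE)
  if (nchar(seq) == 0L) return(empty)
  n <- nchar(seq)
  rc <- reverse_complement(seq)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc
    for (off in 0:2) {
      for (o in .frame_orfs(s, off)) {
        if (nchar(o$aa_seq) < min_aa) next
        if (strand == "+") {
          st <- o$start; en <- o$end
        } else {
          st <- n - o$end + 1L; en <- n - o$start + 1L
        }
        rows[[length(rows) + 1L]] <- data.frame(
          transcript_id = id, strand = strand, frame = off,
          start = st, end = en,
          has_start = o$has_start, has_stop = o$has_stop,
          aa_seq = o$aa_seq, length_aa = nchar(o$aa_seq),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}

#' Representative protein of a transcript: its longest ORF
#'
#' Ties are broken in favour of complete ORFs (start and stop both present),
#' then the forward strand, then the smallest forward-strand start.
#'
#' @inheritParams find_orfs
#' @return A list of class `protein_record` with elements `id`, `aa_seq`,
#'   `length_aa`, `complete`, and `orf` (the winning ORF row).
#' @export
longest_orf_protein <- function(seq, min_aa = 80L, id = NA_character_) {
  orfs <- find_orfs(seq, min_aa = min_aa, id = id)
  if (nrow(orfs) == 0L) {
    stop("no ORF of at least ", min_aa, " aa in transcript ", id)
  }
  complete <- orfs$has_start & orfs$has_stop
  ord <- order(-orfs$length_aa, !complete, orfs$strand != "+", orfs$start)
  best <- orfs[ord[1L], , drop = FALSE]
  structure(list(id = id, aa_seq = best$aa_seq,
                 length_aa = best$length_aa,
                 complete = best$has_start && best$has_stop,
                 orf = best),
            class = "protein_record")
}
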