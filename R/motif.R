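#' Parse a PROSITE-style cysteine-spacing pattern
#'
#' The dialect is `R-x(n,m)-R-...` where `R` is a residue letter and
#' `x(n,m)` (or `x(n)`) a gap of between `n` and `m` unrestricted residues
#' between consecutive anchors. Adjacent anchors written `R-R` mean a gap of
#' exactly 0. A gap token after the final anchor is interpreted as a tail
#' requirement: at least `n` residues must follow the last anchor (the match
#' span still ends at the last anchor).
#'
#' @param pattern Pattern string, e.g. `"C-x(5,6)-C-x(18,19)-C-x(2)-C"`.
#' @param name Motif name carried into the spec.
#' @return An object of class `motif_spec`: list with `name`, `anchors`
#'   (character vector), `gap_min`, `gap_max` (integer vectors, one per
#'   consecutive anchor pair) and `min_tail` (integer).
#' @export
parse_motif <- function(pattern, name = pattern) {
  tokens <- strsplit(pattern, "-", fixed = TRUE)[[1]]
  if (length(tokens) == 0L) stop("empty motif pattern")
  anchors <- character()
  gap_min <- integer()
  gap_max <- integer()
  min_tail <- 0L
  pending_gap <- NULL # gap seen since last anchor
  for (k in seq_along(tokens)) {
    tok <- tokens[k]
    if (grepl("^[A-Z]$", tok)) {
      if (length(anchors) > 0L) {
        if (is.null(pending_gap)) pending_gap <- c(0L, 0L)
        gap_min <- c(gap_min, pending_gap[1L])
        gap_max <- c(gap_max, pending_gap[2L])
      }
      anchors <- c(anchors, tok)
      pending_gap <- NULL
    } else if (grepl("^x\\([0-9]+(,[0-9]+)?\\)$", tok)) {
      if (!is.null(pending_gap)) {
        stop("two consecutive gap tokens at token ", k, " in '", pattern, "'")
      }
      nums <- as.integer(strsplit(gsub("[x()]", "", tok), ",")[[1]])
      if (length(nums) == 1L) nums <- c(nums, nums)
      if (nums[1L] > nums[2L]) {
        stop("gap with min > max at token ", k, " in '", pattern, "'")
      }
      pending_gap <- nums
    } else {
      stop("malformed motif token '", tok, "' at position ", k,
           " in '", pattern, "'")
    }
  }
  if (!is.null(pending_gap)) min_tail <- pending_gap[1L]
  if (length(anchors) < 2L) stop("motif needs at least 2 anchors")
  structure(list(name = name, anchors = anchors,
                 gap_min = gap_min, gap_max = gap_max,
                 min_tail = min_tail),
            class = "motif_spec")
}

#' Built-in cysteine-spacing motif library
#'
#' Five patterns describing insect odorant-binding protein (OBP) and
#' chemosensory protein (CSP) families: the general insect OBP six-cysteine
#' motif, the narrower classic hemipteran OBP motif, the Plus-C OBP motif
#' (extra cysteines and a conserved proline after C6, with a required
#' C-terminal tail), and two published variants of the hemipteran CSP
#' four-cysteine motif.
#'
#' @return Named list of `motif_spec` objects: `OBP_GENERAL`, `OBP_CLASSIC`,
#'   `OBP_PLUSC`, `CSP_METHODS`, `CSP_RESULTS`.
#' @export
motif_library <- function() {
  list(
    OBP_GENERAL = parse_motif(
      "C-x(15,39)-C-x(3)-C-x(21,44)-C-x(7,12)-C-x(8)-C", "OBP_GENERAL"),
    OBP_CLASSIC = parse_motif(
      "C-x(22,32)-C-x(3)-C-x(36,46)-C-x(8,14)-C-x(8)-C", "OBP_CLASSIC"),
    OBP_PLUSC = parse_motif(
      "C-x(20,41)-C-x(3)-C-x(41,46)-C-x(19,29)-C-x(9)-C-x(8)-C-P-x(9,10)-C-x(9,10)",
      "OBP_PLUSC"),
    CSP_METHODS = parse_motif(
      "C-x(6,8)-C-x(16,21)-C-x(2)-C", "CSP_METHODS"),
    CSP_RESULTS = parse_motif(
      "C-x(5,6)-C-x(18,19)-C-x(2)-C", "CSP_RESULTS")
  )
}

#' Enumerate all anchor assignments of a motif in a protein
#'
#' Backtracking search over candidate anchor positions with gap-range
#' pruning. A protein "has the motif" iff at least one assignment exists;
#' all distinct assignments are returned, ordered lexicographically by
#' anchor positions. Gap residues are unrestricted (they may themselves be
#' anchor letters), so greedy left-to-right matching would miss assignments;
#' the search is exhaustive.
#'
#' @param protein Amino-acid string.
#' @param motif A `motif_spec`.
#' @param max_matches Enumeration cap; exceeding it drops the excess
#'   assignments with a warning.
#' @return List of integer vectors of 1-based anchor positions (possibly
#'   empty).
#' @export
scan_motif <- function(protein, motif, max_matches = 10000L) {
  stopifnot(inherits(motif, "motif_spec"), length(protein) == 1L)
  if (grepl("[^A-Z]", protein)) stop("protein must be an uppercase aa string")
  chars <- strsplit(protein, "")[[1]]
  n <- length(chars)
  k <- length(motif$anchors)
  cand <- lapply(motif$anchors, function(a) which(chars == a))
  if (any(vapply(cand, length, 0L) == 0L)) return(list())
  # need_after[i]: minimal residues required beyond anchor i's position to
  # satisfy the remaining gaps, anchors and tail
  need_after <- rev(cumsum(rev(c(motif$gap_min + 1L, motif$min_tail))))
  matches <- list()
  truncated <- FALSE
  recurse <- function(level, prev_pos, acc) {
    if (truncated) return()
    for (p in cand[[level]]) {
      if (level > 1L) {
        gap <- p - prev_pos - 1L
        if (gap < motif$gap_min[level - 1L]) next
        if (gap > motif$gap_max[level - 1L]) break # candidates ascend
      }
      if (n - p < need_after[level]) next
      if (level == k) {
        if (length(matches) >= max_matches) {
          truncated <<- TRUE
          return()
        }
        matches[[length(matches) + 1L]] <<- c(acc, p)
      } else {
        recurse(level + 1L, p, c(acc, p))
      }
    }
  }
  recurse(1L, 0L, integer())
  if (truncated) {
    warning("match enumeration capped at ", max_matches,
            " assignments; result truncated")
  }
  matches
}

#' Does the protein contain at least one assignment of the motif?
#'
#' @inheritParams scan_motif
#' @return Logical scalar.
#' @export
has_motif <- function(protein, motif) {
  length(scan_motif(protein, motif, max_matches = 1L)) > 0L
}

#' Classify a protein into OBP subfamilies / CSP
#'
#' Each motif is tested independently (the classic hemipteran ranges overlap
#' the general insect ranges but neither contains the other, so a classic
#' match does not imply a general match). The primary family follows the
#' fixed precedence Plus-C > classic > general > CSP > none.
#'
#' @param protein Amino-acid string.
#' @param motifs Motif library, as from [motif_library()].
#' @param csp_variant Which CSP pattern sets the `CSP` flag,
#'   `"CSP_RESULTS"` (default) or `"CSP_METHODS"`.
#' @return List of class `family_call`: `flags` (character vector drawn from
#'   OBP_GENERAL/OBP_CLASSIC/OBP_PLUSC/CSP), `primary_family`, and `matches`
#'   (named list of anchor-assignment lists for the flagged motifs).
#' @export
classify_protein <- function(protein, motifs = motif_library(),
                             csp_variant = c("CSP_RESULTS", "CSP_METHODS")) {
  if (length(motifs) == 0L) stop("empty motif library")
  csp_variant <- match.arg(csp_variant)
  tested <- c(OBP_GENERAL = "OBP_GENERAL", OBP_CLASSIC = "OBP_CLASSIC",
              OBP_PLUSC = "OBP_PLUSC", CSP = csp_variant)
  flags <- character()
  hits <- list()
  for (flag in names(tested)) {
    spec <- motifs[[tested[[flag]]]]
    if (is.null(spec)) stop("motif library lacks pattern ", tested[[flag]])
    m <- scan_motif(protein, spec)
    if (length(m) > 0L) {
      flags <- c(flags, flag)
      hits[[flag]] <- m
    }
  }
  precedence <- c("OBP_PLUSC", "OBP_CLASSIC", "OBP_GENERAL", "CSP")
  primary <- precedence[precedence %in% flags][1L]
  if (is.na(primary)) primary <- "NONE"
  structure(list(flags = flags, primary_family = primary, matches = hits),
            class = "family_call")
}

#' Mine candidate OBP/CSP transcripts from a transcriptome
#'
#' For each transcript the longest-ORF protein is extracted and classified;
#' transcripts whose protein matches no family motif, or whose longest ORF
#' is shorter than `min_aa`, are dropped.
#'
#' @param transcripts Data frame from [read_fasta()].
#' @param motifs Motif library.
#' @param min_aa Minimum protein length (default 80; the smallest mature
#'   chemosensory proteins run ~110 aa, so 80 leaves margin while
#'   suppressing spurious ORFs).
#' @param csp_variant Active CSP pattern, see [classify_protein()].
#' @return Data frame with one row per candidate: `transcript_id`,
#'   `primary_family`, `flags` (comma-joined), `length_aa`, `complete_orf`,
#'   `aa_seq`, `anchor_positions` (1-based, comma-joined, first assignment
#'   of the primary family's motif).
#' @export
mine_candidates <- function(transcripts, motifs = motif_library(),
                            min_aa = 80L,
                            csp_variant = c("CSP_RESULTS", "CSP_METHODS")) {
  csp_variant <- match.arg(csp_variant)
  empty <- data.frame(transcript_id = character(), primary_family = character(),
                      flags = character(), length_aa = integer(),
                      complete_orf = logical(), aa_seq = character(),
                      anchor_positions = character(), stringsAsFactors = FALSE)
  if (nrow(transcripts) == 0L) return(empty)
  rows <- list()
  for (i in seq_len(nrow(transcripts))) {
    prot <- tryCatch(
      longest_orf_protein(transcripts$seq[i], min_aa = min_aa,
                          id = transcripts$id[i]),
      error = function(e) NULL)
    if (is.null(prot)) next
    call <- classify_protein(prot$aa_seq, motifs, csp_variant)
    if (call$primary_family == "NONE") next
    anchors <- call$matches[[call$primary_family]][[1L]]
    rows[[length(rows) + 1L]] <- data.frame(
      transcript_id = prot$id,
      primary_family = call$primary_family,
      flags = paste(call$flags, collapse = ","),
      length_aa = prot$length_aa,
      complete_orf = prot$complete,
      aa_seq = prot$aa_seq,
      anchor_positions = paste(anchors, collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}
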