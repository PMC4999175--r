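#' Read a nucleotide FASTA file of assembled transcripts
#'
#' Parses a (possibly line-wrapped) FASTA file into a data frame of
#' transcripts. The record id is the header text up to the first whitespace;
#' any remainder becomes the description. Sequences are uppercased and RNA
#' `U` is mapped to `T` so that all downstream code sees a single canonical
#' DNA alphabet.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id`, `seq`, `description`, one row per
#'   record, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    return(data.frame(id = character(), seq = character(),
                      description = character(), stringsAsFactors = FALSE))
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  if (any(ids == "")) stop("FASTA record with empty id")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate FASTA ids: ", paste(unique(dup), collapse = ", "))
  }
  if (any(nchar(seqs) == 0L)) {
    stop("empty FASTA record: ", paste(ids[nchar(seqs) == 0L], collapse = ", "))
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("non-nucleotide characters in record(s): ",
         paste(ids[bad], collapse = ", "))
  }
  data.frame(id = ids, seq = unname(seqs), description = unname(desc),
             stringsAsFactors = FALSE)
}

#' Write transcripts or proteins to FASTA
#'
#' @param x A data frame with columns `id` and `seq` (optionally
#'   `description`), as returned by [read_fasta()].
#' @param path Output path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  stopifnot(is.data.frame(x), all(c("id", "seq") %in% names(x)))
  headers <- x$id
  if (!is.null(x$description)) {
    has_desc <- !is.na(x$description) & nzchar(x$description)
    headers[has_desc] <- paste(x$id[has_desc], x$description[has_desc])
  }
  set <- Biostrings::BStringSet(x$seq)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a per-gene read-count table with library sizes
#'
#' The count file is a CSV with header `gene_id,length_bp,<condition>...`;
#' the library-size file is a one-row CSV keyed by the same condition names.
#' Library sizes are supplied separately rather than inferred by summing
#' counts, because the total of uniquely aligned reads in a sequencing
#' library is a superset of the reads landing on the genes tabulated.
#'
#' @param counts_path CSV of per-gene counts.
#' @param lib_sizes_path One-row CSV of per-condition library sizes.
#' @return An object of class `count_table`: a list with elements `counts`
#'   (data frame `gene_id`, `length_bp`, one integer column per condition)
#'   and `lib_sizes` (named numeric vector).
#' @export
read_count_table <- function(counts_path, lib_sizes_path) {
  counts <- utils::read.csv(counts_path, stringsAsFactors = FALSE,
                            check.names = FALSE)
  libs <- utils::read.csv(lib_sizes_path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!all(c("gene_id", "length_bp") %in% names(counts))) {
    stop("count table must have columns gene_id and length_bp")
  }
  lib_sizes <- as.numeric(libs[1L, ])
  names(lib_sizes) <- names(libs)
  make_count_table(counts, lib_sizes)
}

#' Construct and validate a count table
#'
#' @param counts Data frame `gene_id`, `length_bp`, one column per condition.
#' @param lib_sizes Named vector of total uniquely aligned reads (N) per
#'   condition.
#' @return A validated `count_table` object.
#' @export
make_count_table <- function(counts, lib_sizes) {
  cond_cols <- setdiff(names(counts), c("gene_id", "length_bp"))
  if (length(cond_cols) == 0L) stop("count table has no condition columns")
  if (anyDuplicated(counts$gene_id)) {
    stop("duplicate gene_id in count table: ",
         counts$gene_id[duplicated(counts$gene_id)][1L])
  }
  unknown <- setdiff(cond_cols, names(lib_sizes))
  if (length(unknown) > 0L) {
    stop("conditions without a library size: ", paste(unknown, collapse = ", "))
  }
  if (!is.numeric(counts$length_bp) || any(counts$length_bp < 1) ||
      any(counts$length_bp != round(counts$length_bp))) {
    stop("length_bp must be positive integers")
  }
  for (cc in cond_cols) {
    v <- counts[[cc]]
    if (!is.numeric(v) || any(is.na(v))) {
      stop("non-numeric count in condition ", cc)
    }
    if (any(v != round(v))) stop("non-integer count in condition ", cc)
    if (any(v < 0)) stop("negative count in condition ", cc)
    if (lib_sizes[[cc]] < max(v)) {
      stop("library size for ", cc, " smaller than a per-gene count")
    }
  }
  if (any(!is.finite(lib_sizes)) || any(lib_sizes < 1)) {
    stop("library sizes must be positive")
  }
  structure(list(counts = counts, lib_sizes = lib_sizes[cond_cols]),
            class = "count_table")
}

#' Read a long-format qPCR Ct table
#'
#' @param path CSV with columns `gene_id,sample_id,group_label,replicate,ct`.
#' @return A validated data frame of class `ct_table`.
#' @export
read_ct_table <- function(path) {
  ct <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(ct = "character"))
  make_ct_table(ct)
}

#' Construct and validate a Ct table
#'
#' @param ct Data frame with columns `gene_id`, `sample_id`, `group_label`,
#'   `replicate`, `ct`.
#' @return The validated data frame, classed `ct_table`.
#' @export
make_ct_table <- function(ct) {
  need <- c("gene_id", "sample_id", "group_label", "replicate", "ct")
  if (!all(need %in% names(ct))) {
    stop("Ct table must have columns ", paste(need, collapse = ","))
  }
  ct_num <- suppressWarnings(as.numeric(ct$ct))
  if (any(is.na(ct_num))) {
    stop("non-numeric ct value at row(s) ",
         paste(which(is.na(ct_num)), collapse = ", "))
  }
  ct$ct <- ct_num
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0)) {
    stop("ct values must be finite and > 0")
  }
  key <- paste(ct$gene_id, ct$sample_id, ct$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    d <- ct[duplicated(key), , drop = FALSE][1L, ]
    stop("duplicate (gene, sample, replicate): ",
         paste(d$gene_id, d$sample_id, d$replicate, sep = "/"))
  }
  class(ct) <- c("ct_table", "data.frame")
  ct
}

#' Write the candidate report
#'
#' Tab-separated, one row per candidate, ordered by family (OBP subfamilies
#' before CSP) then id; mirrors the layout of a gene catalogue table
#' (name, length in aa, completeness, motif evidence).
#'
#' @param candidates Candidate data frame from [mine_candidates()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_candidate_report <- function(candidates, path) {
  cols <- c("transcript_id", "primary_family", "flags", "length_aa",
            "complete_orf", "anchor_positions")
  if (nrow(candidates) > 0L) {
    fam_rank <- match(candidates$primary_family,
                      c("OBP_PLUSC", "OBP_CLASSIC", "OBP_GENERAL", "CSP"))
    ord <- order(fam_rank, candidates$transcript_id)
    candidates <- candidates[ord, cols, drop = FALSE]
  } else {
    candidates <- candidates[, cols, drop = FALSE]
  }
  utils::write.table(candidates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
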