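# Stage runners behind the command-line entry point (inst/cli/chemomine.R).
# Each takes file paths in, writes deterministic TSV/FASTA/newick outputs,
# and returns its result invisibly for programmatic use.

#' Read a protein (or aligned protein) FASTA file
#'
#' @param path FASTA path; sequences over the amino-acid alphabet, `X` and
#'   the gap character `-`.
#' @return Data frame with `id`, `seq`, `description`.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ", ids[duplicated(ids)][1L])
  }
  bad <- grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "X*-]"), seqs)
  if (any(bad)) stop("non-protein characters in record ", ids[bad][1L])
  data.frame(id = ids, seq = unname(seqs), description = unname(desc),
             stringsAsFactors = FALSE)
}

#' Mine candidate chemosensory genes from a transcriptome FASTA
#'
#' @param fasta Path to the nucleotide FASTA of assembled transcripts.
#' @param out_dir Output directory (created if needed); writes
#'   `candidates.tsv` and `candidate_proteins.fasta`.
#' @param min_aa Minimum longest-ORF protein length.
#' @param csp_variant Active CSP motif variant.
#' @return The candidate data frame, invisibly.
#' @export
run_mine <- function(fasta, out_dir, min_aa = 80L,
                     csp_variant = c("CSP_RESULTS", "CSP_METHODS")) {
  csp_variant <- match.arg(csp_variant)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  transcripts <- read_fasta(fasta)
  cand <- mine_candidates(transcripts, min_aa = min_aa,
                          csp_variant = csp_variant)
  write_candidate_report(cand, file.path(out_dir, "candidates.tsv"))
  prot <- data.frame(id = cand$transcript_id, seq = cand$aa_seq,
                     description = cand$primary_family,
                     stringsAsFactors = FALSE)
  write_fasta(prot, file.path(out_dir, "candidate_proteins.fasta"))
  counts <- table(factor(cand$primary_family,
                         c("OBP_PLUSC", "OBP_CLASSIC", "OBP_GENERAL", "CSP")))
  message("candidates by family: ",
          paste(names(counts), counts, sep = "=", collapse = ", "))
  invisible(cand)
}

#' Convert counts to RPKM and compare conditions
#'
#' @param counts_csv Per-gene counts CSV (`gene_id,length_bp,<cond>...`).
#' @param lib_sizes_csv One-row CSV of per-condition library sizes.
#' @param out_dir Output directory; writes `rpkm.tsv` and, with two or more
#'   conditions, `rpkm_ratio.tsv`.
#' @param numerator,denominator Conditions for the ratio (default: first
#'   two).
#' @return The `rpkm_table` result, invisibly.
#' @export
run_quantify <- function(counts_csv, lib_sizes_csv, out_dir,
                         numerator = NULL, denominator = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- read_count_table(counts_csv, lib_sizes_csv)
  res <- rpkm_table(counts, numerator, denominator)
  utils::write.table(res$records, file.path(out_dir, "rpkm.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$comparison)) {
    utils::write.table(res$comparison, file.path(out_dir, "rpkm_ratio.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(res)
}

#' Normalize qPCR data and letter-group the expression profiles
#'
#' Runs multi-reference normalization, then a one-way ANOVA with LSD letter
#' display per gene across the groups of the Ct table (biological samples
#' are the replication units; technical replicates are averaged first).
#'
#' @param ct_csv Long-format Ct CSV.
#' @param reference_genes Reference gene ids.
#' @param out_dir Output directory; writes `normalized_expression.tsv` and
#'   `anova_letters.tsv`.
#' @param calibrator Calibrator sample id, or `NULL` for no fold column.
#' @param efficiencies Named per-gene amplification factors (default 2).
#' @param alpha LSD significance level.
#' @return List with `expression` and `letters` data frames, invisibly.
#' @export
run_qpcr <- function(ct_csv, reference_genes, out_dir, calibrator = NULL,
                     efficiencies = NULL, alpha = 0.05) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ct <- read_ct_table(ct_csv)
  norm <- vandesompele_normalize(ct, reference_genes, efficiencies, calibrator)
  utils::write.table(norm, file.path(out_dir, "normalized_expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  targets <- setdiff(unique(norm$gene_id), reference_genes)
  rows <- list()
  for (g in targets) {
    sub <- norm[norm$gene_id == g, ]
    if (length(unique(sub$group_label)) < 2L) next
    reps <- table(sub$group_label)
    if (any(reps < 2L)) next
    res <- anova_lsd(sub$norm, sub$group_label, alpha = alpha)
    rows[[g]] <- data.frame(gene_id = g, group = names(res$letters),
                            mean_norm = as.vector(res$means[names(res$letters)]),
                            F = res$F, p = res$p,
                            letters = unname(res$letters),
                            stringsAsFactors = FALSE)
  }
  letters_df <- if (length(rows) > 0L) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(gene_id = character(), group = character(),
               mean_norm = numeric(), F = numeric(), p = numeric(),
               letters = character(), stringsAsFactors = FALSE)
  }
  utils::write.table(letters_df, file.path(out_dir, "anova_letters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(expression = norm, letters = letters_df))
}

#' Identity matrix and bootstrapped NJ tree for a protein set
#'
#' @param fasta Protein FASTA (aligned or unaligned; unaligned input is
#'   aligned with [center_star_align()]).
#' @param out_dir Output directory; writes `tree.nwk` and
#'   `identity_matrix.tsv`.
#' @param aligned Is the input already a multiple alignment?
#' @param bootstrap Number of bootstrap replicates.
#' @param seed Seed for bootstrap resampling.
#' @return List with `tree` (`phylo` with supports) and `identity`
#'   (the [identity_matrix()] result), invisibly.
#' @export
run_tree <- function(fasta, out_dir, aligned = FALSE, bootstrap = 1000L,
                     seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prot <- read_protein_fasta(fasta)
  if (nrow(prot) < 3L) stop("need at least 3 sequences for a tree")
  seqs <- stats::setNames(prot$seq, prot$id)
  aln <- if (aligned) seqs else center_star_align(gsub("-", "", seqs))
  idm <- identity_matrix(stats::setNames(gsub("-", "", seqs), prot$id))
  tree <- bootstrap_supports(aln, n_reps = bootstrap, seed = seed)
  write_newick(tree, file.path(out_dir, "tree.nwk"))
  utils::write.table(round(idm$percent, 2),
                     file.path(out_dir, "identity_matrix.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  message(sprintf("identity range: %.2f-%.2f%%", idm$range[1], idm$range[2]))
  invisible(list(tree = tree, identity = idm))
}
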