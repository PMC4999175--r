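# Generators emulating the data-generating structure the pipeline assumes:
# motif-planted proteins, ORF-bearing transcripts, Poisson read counts with
# known true RPKM, Ct tables with stable references and planted folds, and
# alignments evolved on a known tree. Every generator is a pure function of
# its arguments and seed (seed = NULL uses the current RNG stream, so
# composite generators can drive several of them from one seed).

.fill_alphabet <- function(spec, exclude_anchors = TRUE) {
  if (exclude_anchors) setdiff(AA_ALPHABET, unique(spec$anchors)) else AA_ALPHABET
}

.maybe_seed <- function(seed, code) {
  if (is.null(seed)) code else with_seed(seed, code)
}

#' Plant a motif into a random protein
#'
#' Anchors are placed with exactly the requested gaps; gap and flank
#' residues are drawn uniformly from the amino-acid alphabet excluding the
#' spec's anchor letters (default), so the planted assignment is provably
#' the unique match. Set `exclude_anchors = FALSE` for stress tests where
#' spurious anchor letters may occur.
#'
#' @param spec A `motif_spec`.
#' @param gaps Integer gap vector, componentwise inside the spec's ranges.
#' @param flanks Lengths of the N- and C-terminal flanks; the C-terminal
#'   flank must be at least the spec's tail requirement.
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param exclude_anchors Exclude anchor letters from fill residues.
#' @return List with `protein` and `positions` (1-based planted anchor
#'   positions).
#' @export
plant_motif <- function(spec, gaps, flanks = c(5L, 5L), seed = NULL,
                        exclude_anchors = TRUE) {
  stopifnot(inherits(spec, "motif_spec"))
  if (length(gaps) != length(spec$gap_min)) {
    stop("expected ", length(spec$gap_min), " gaps, got ", length(gaps))
  }
  bad <- gaps < spec$gap_min | gaps > spec$gap_max
  if (any(bad)) {
    stop("gap ", which(bad)[1L], " = ", gaps[which(bad)[1L]],
         " outside range [", spec$gap_min[which(bad)[1L]], ",",
         spec$gap_max[which(bad)[1L]], "]")
  }
  if (flanks[2L] < spec$min_tail) {
    stop("C-terminal flank shorter than the motif's tail requirement (",
         spec$min_tail, ")")
  }
  fill <- .fill_alphabet(spec, exclude_anchors)
  .maybe_seed(seed, {
    k <- length(spec$anchors)
    pieces <- character(0)
    pieces <- paste(sample(fill, flanks[1L], replace = TRUE), collapse = "")
    positions <- integer(k)
    pos <- flanks[1L]
    for (i in seq_len(k)) {
      pieces <- paste0(pieces, spec$anchors[i])
      pos <- pos + 1L
      positions[i] <- pos
      if (i < k) {
        pieces <- paste0(pieces,
                         paste(sample(fill, gaps[i], replace = TRUE),
                               collapse = ""))
        pos <- pos + gaps[i]
      }
    }
    pieces <- paste0(pieces,
                     paste(sample(fill, flanks[2L], replace = TRUE),
                           collapse = ""))
    list(protein = pieces, positions = positions)
  })
}

#' Perturb one gap of a planted motif
#'
#' Inserts (`delta > 0`) or deletes (`delta < 0`) non-anchor residues
#' inside the chosen gap, producing negative controls whose spacing leaves
#' the spec's range.
#'
#' @param protein Protein string from [plant_motif()].
#' @param positions Planted anchor positions.
#' @param gap_index Which gap (1-based, between anchors `gap_index` and
#'   `gap_index + 1`) to perturb.
#' @param delta Change in gap length; the new gap must be >= 0.
#' @param spec Optional `motif_spec`; its anchor letters are excluded from
#'   inserted residues (default exclusion: `C` and `P`).
#' @param seed Integer seed or `NULL`.
#' @return List with the new `protein` and updated `positions`.
#' @export
perturb_gap <- function(protein, positions, gap_index, delta,
                        spec = NULL, seed = NULL) {
  stopifnot(gap_index >= 1L, gap_index < length(positions))
  gap <- positions[gap_index + 1L] - positions[gap_index] - 1L
  if (gap + delta < 0L) stop("perturbation makes gap negative")
  if (delta == 0L) return(list(protein = protein, positions = positions))
  fill <- if (is.null(spec)) setdiff(AA_ALPHABET, c("C", "P")) else
    .fill_alphabet(spec, TRUE)
  chars <- strsplit(protein, "")[[1]]
  at <- positions[gap_index] # insert/delete just after this anchor
  .maybe_seed(seed, {
    if (delta > 0L) {
      ins <- sample(fill, delta, replace = TRUE)
      chars <- append(chars, ins, after = at)
    } else {
      chars <- chars[-seq.int(at + 1L, at - delta)]
    }
    positions[seq.int(gap_index + 1L, length(positions))] <-
      positions[seq.int(gap_index + 1L, length(positions))] + delta
    list(protein = paste(chars, collapse = ""), positions = positions)
  })
}

# codon choices per amino acid (stops excluded)
.rev_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))[AA_ALPHABET]
}

# Uniform-synonymous-codon reverse translation using the current RNG.
.reverse_translate <- function(protein) {
  rc <- .rev_codons()
  aas <- strsplit(protein, "")[[1]]
  paste(vapply(aas, function(a) {
    opts <- rc[[a]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, ""), collapse = "")
}

# Wrap an ORF protein into a transcript whose longest ORF is exactly that
# protein. `complete` adds ATG...stop plus UTRs; incomplete transcripts are
# 5'-truncated (no start codon, stop present). Rejection-samples UTRs until
# the planted protein is recovered, so downstream recovery is guaranteed by
# construction.
.build_transcript <- function(protein, complete, min_aa = 80L,
                              utr5_range = c(20L, 60L),
                              utr3_range = c(20L, 60L), max_tries = 100L) {
  nts <- c("A", "C", "G", "T")
  stops <- c("TAA", "TAG", "TGA")
  chars <- strsplit(protein, "")[[1]]
  if (!complete && chars[1L] == "M") {
    chars[1L] <- "A" # a 5'-truncated record must not begin at a start codon
    protein <- paste(chars, collapse = "")
  }
  expected <- if (complete) paste0("M", protein) else protein
  if (nchar(expected) < min_aa) {
    stop("planted protein (", nchar(expected), " aa) is shorter than min_aa (",
         min_aa, "); enlarge the flanks or lower min_aa")
  }
  for (try in seq_len(max_tries)) {
    cds <- .reverse_translate(protein)
    stop_codon <- sample(stops, 1L)
    utr3 <- paste(sample(nts, sample(utr3_range[1L]:utr3_range[2L], 1L),
                         replace = TRUE), collapse = "")
    if (complete) {
      utr5 <- paste(sample(nts, sample(utr5_range[1L]:utr5_range[2L], 1L),
                           replace = TRUE), collapse = "")
      tx <- paste0(utr5, "ATG", cds, stop_codon, utr3)
    } else {
      tx <- paste0(cds, stop_codon, utr3)
    }
    rec <- tryCatch(longest_orf_protein(tx, min_aa = min_aa),
                    error = function(e) NULL)
    if (!is.null(rec) && rec$aa_seq == expected &&
        rec$complete == complete) {
      return(list(seq = tx, protein = expected))
    }
  }
  stop("failed to wrap protein into a transcript after ", max_tries, " tries")
}

#' Generate a synthetic transcript set with known family truth
#'
#' Each plan plants a motif, reverse-translates the protein with uniform
#' synonymous codons, and wraps it in random UTRs such that the planted
#' protein is exactly the transcript's longest ORF. Negatives are
#' nucleotide-shuffled copies of the positives, re-shuffled until they
#' contain no classifiable candidate.
#'
#' @param plans List of plans, each a list with `id`, `spec` (a `motif_spec`
#'   or the name of a built-in), `gaps`, `flanks`, and optional `complete`
#'   (default `TRUE`).
#' @param n_negatives Number of shuffled negative transcripts.
#' @param seed Integer seed.
#' @param min_aa Minimum ORF length used during construction checks.
#' @param motifs Motif library for resolving spec names and vetting
#'   negatives.
#' @return List with `transcripts` (data frame `id`, `seq`, `description`)
#'   and `truth` (`id`, `family`, `complete`, `protein`).
#' @export
gen_transcript_set <- function(plans, n_negatives = 0L, seed = 1L,
                               min_aa = 80L, motifs = motif_library()) {
  with_seed(seed + SEED_OFFSETS[["transcripts"]], {
    tx_rows <- list()
    truth_rows <- list()
    for (p in plans) {
      spec <- if (is.character(p$spec)) motifs[[p$spec]] else p$spec
      if (is.null(spec)) stop("unknown motif spec in plan ", p$id)
      complete <- if (is.null(p$complete)) TRUE else p$complete
      flanks <- if (is.null(p$flanks)) c(5L, max(5L, spec$min_tail)) else p$flanks
      planted <- plant_motif(spec, p$gaps, flanks)
      built <- .build_transcript(planted$protein, complete, min_aa = min_aa)
      tx_rows[[p$id]] <- data.frame(id = p$id, seq = built$seq,
                                    description = paste0("planted:", spec$name),
                                    stringsAsFactors = FALSE)
      truth_rows[[p$id]] <- data.frame(id = p$id, family = spec$name,
                                       complete = complete,
                                       protein = built$protein,
                                       stringsAsFactors = FALSE)
    }
    pos_seqs <- vapply(tx_rows, function(r) r$seq, "")
    for (k in seq_len(n_negatives)) {
      base <- pos_seqs[[(k - 1L) %% length(pos_seqs) + 1L]]
      id <- sprintf("neg%03d", k)
      repeat {
        shuf <- paste(sample(strsplit(base, "")[[1]]), collapse = "")
        df <- data.frame(id = id, seq = shuf, description = "shuffled",
                         stringsAsFactors = FALSE)
        if (nrow(mine_candidates(df, motifs, min_aa = min_aa)) == 0L) {
          tx_rows[[id]] <- df
          truth_rows[[id]] <- data.frame(id = id, family = "NONE",
                                         complete = NA, protein = NA_character_,
                                         stringsAsFactors = FALSE)
          break
        }
      }
    }
    list(transcripts = do.call(rbind, c(tx_rows, list(make.row.names = FALSE))),
         truth = do.call(rbind, c(truth_rows, list(make.row.names = FALSE))))
  })
}

#' Simulate a count table with known true RPKM
#'
#' Per-gene counts are Poisson with mean `rpkm * N * L / 1e9`; the recorded
#' library size is `N` itself, not the sum of the tabulated counts.
#'
#' @param true_rpkm Named vector of true RPKM values per gene.
#' @param L Named vector of gene lengths (bases), same genes.
#' @param N Named vector of library sizes per condition.
#' @param seed Integer seed.
#' @return A `count_table`.
#' @export
sim_counts <- function(true_rpkm, L, N, seed = 1L) {
  stopifnot(all(true_rpkm >= 0), all(L >= 1), all(N >= 1))
  genes <- names(true_rpkm)
  if (is.null(genes) || is.null(names(N))) stop("named inputs required")
  with_seed(seed + SEED_OFFSETS[["counts"]], {
    counts <- data.frame(gene_id = genes, length_bp = as.integer(L[genes]),
                         stringsAsFactors = FALSE)
    for (cond in names(N)) {
      mu <- true_rpkm * N[[cond]] * L[genes] / 1e9
      if (any(mu > 1e9)) stop("Poisson mean overflow")
      counts[[cond]] <- stats::rpois(length(genes), mu)
    }
    make_count_table(counts, N)
  })
}

#' Simulate a long-format qPCR Ct table with planted fold changes
#'
#' `Ct(gene, sample, rep) = base_ct[gene] - log_E(fold[gene, sample]) +
#' shift[sample] + Normal(0, sd)`. Reference genes are rows of the fold
#' matrix fixed at 1; the per-sample shift models loading differences shared
#' by every gene of a sample, which multi-reference normalization must
#' cancel.
#'
#' @param folds Genes x samples matrix of true fold changes (dimnames
#'   required; reference-gene rows should be 1).
#' @param base_ct Named per-gene baseline Ct.
#' @param efficiency Scalar or named per-gene amplification factor.
#' @param shifts Named per-sample loading shift in cycles (default 0).
#' @param groups Named per-sample group label (default the sample id).
#' @param n_reps Technical replicates per (gene, sample).
#' @param noise_sd Gaussian Ct noise standard deviation.
#' @param seed Integer seed.
#' @return A `ct_table` data frame.
#' @export
sim_ct_table <- function(folds, base_ct, efficiency = 2, shifts = NULL,
                         groups = NULL, n_reps = 3L, noise_sd = 0,
                         seed = 1L) {
  stopifnot(is.matrix(folds), !is.null(dimnames(folds)), all(folds > 0),
            noise_sd >= 0)
  genes <- rownames(folds)
  samples <- colnames(folds)
  if (length(efficiency) == 1L && is.null(names(efficiency))) {
    efficiency <- stats::setNames(rep(efficiency, length(genes)), genes)
  }
  if (any(efficiency <= 0)) stop("amplification factors must be positive")
  if (is.null(shifts)) shifts <- stats::setNames(rep(0, length(samples)), samples)
  if (is.null(groups)) groups <- stats::setNames(samples, samples)
  with_seed(seed + SEED_OFFSETS[["ct"]], {
    rows <- expand.grid(gene_id = genes, sample_id = samples,
                        replicate = seq_len(n_reps), stringsAsFactors = FALSE)
    ct <- base_ct[rows$gene_id] -
      log(folds[cbind(rows$gene_id, rows$sample_id)]) /
        log(efficiency[rows$gene_id]) +
      shifts[rows$sample_id] +
      stats::rnorm(nrow(rows), 0, noise_sd)
    out <- data.frame(gene_id = rows$gene_id, sample_id = rows$sample_id,
                      group_label = unname(groups[rows$sample_id]),
                      replicate = rows$replicate, ct = unname(ct),
                      stringsAsFactors = FALSE)
    make_ct_table(out)
  })
}

#' Evolve an alignment on a known tree
#'
#' A random root protein is mutated independently along each branch with
#' per-site substitution probability `1 - exp(-rate * length)`; a
#' substituted site changes to a uniformly chosen different residue. No
#' indels are introduced, so the leaf sequences are trivially aligned.
#'
#' @param tree A `phylo` object or newick string.
#' @param root_length Root sequence length (>= 50).
#' @param rate Substitution rate per unit branch length.
#' @param seed Integer seed.
#' @return List with `alignment` (named character vector over the tips) and
#'   `tree` (the input tree as `phylo`).
#' @export
sim_alignment_on_tree <- function(tree, root_length = 100L, rate = 1,
                                  seed = 1L) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"), root_length >= 50L,
            rate >= 0)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  tree <- stats::reorder(tree, "cladewise") # parents before children
  with_seed(seed + SEED_OFFSETS[["alignment"]], {
    seqs <- vector("list", ntip + tree$Nnode)
    seqs[[root]] <- sample(AA_ALPHABET, root_length, replace = TRUE)
    for (e in seq_len(nrow(tree$edge))) {
      parent <- tree$edge[e, 1L]
      child <- tree$edge[e, 2L]
      len <- tree$edge.length[e]
      p_sub <- 1 - exp(-rate * len)
      s <- seqs[[parent]]
      mut <- stats::runif(root_length) < p_sub
      if (any(mut)) {
        s[mut] <- vapply(s[mut], function(a) {
          sample(setdiff(AA_ALPHABET, a), 1L)
        }, "")
      }
      seqs[[child]] <- s
    }
    aln <- vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""), "")
    names(aln) <- tree$tip.label
    list(alignment = aln, tree = tree)
  })
}
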