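# Synthetic stand-ins for the deposited GenBank records KU140605-KU140622.
# The real mRNA sequences can be fetched with scripts/fetch_accessions.R
# when network access is available; these surrogates reproduce the
# catalogued properties of each record (protein length, ORF completeness,
# and the published cysteine-spacing characteristics: which OBPs carry the
# classic hemipteran motif, the deviant C1-C2 / C3-C4 / C4-C5 spacings of
# OBP1 and OBP4, the Plus-C architecture of OBP5/6, and the CSP motif of
# all five CSPs), so the mining pipeline can be exercised end to end
# offline. They are synthetic: agreement with the deposited sequences
# themselves is only testable after a fetch.

.accession_catalogue <- function() {
  # gene, accession, precursor length (aa), complete ORF, family plan
  read.table(header = TRUE, stringsAsFactors = FALSE, text = "
gene       accession length complete plan
SaveOBP1   KU140605  152    TRUE     OBP_DEVIANT1
SaveOBP2   KU140606  243    TRUE     OBP_CLASSIC
SaveOBP3   KU140607  141    TRUE     OBP_CLASSIC
SaveOBP4   KU140608  199    TRUE     OBP_DEVIANT4
SaveOBP5   KU140609  221    TRUE     OBP_PLUSC
SaveOBP6   KU140610  215    TRUE     OBP_PLUSC
SaveOBP7   KU140611  149    TRUE     OBP_CLASSIC
SaveOBP8   KU140612  162    TRUE     OBP_CLASSIC
SaveOBP9   KU140613  166    TRUE     OBP_CLASSIC
SaveOBP10  KU140614  143    TRUE     OBP_CLASSIC
SaveOBP13  KU140615  112    FALSE    OBP_CLASSIC
SaveOBP14  KU140616  167    TRUE     OBP_CLASSIC
SaveOBP15  KU140617  175    TRUE     OBP_CLASSIC
SaveCSP1   KU140618  118    FALSE    CSP
SaveCSP2   KU140619  147    TRUE     CSP
SaveCSP3   KU140620  138    TRUE     CSP
SaveCSP4   KU140621  157    TRUE     CSP
SaveCSP5   KU140622  231    TRUE     CSP
")
}

# Gap vectors per plan. The deviant spacings follow the published
# descriptions: OBP1 has 47 residues between C3 and C4; OBP4 has 49 between
# C1 and C2 and 21 between C4 and C5; both fall outside the classic and
# general OBP ranges.
.accession_gaps <- list(
  OBP_CLASSIC = c(25L, 3L, 40L, 10L, 8L),
  OBP_DEVIANT1 = c(25L, 3L, 47L, 9L, 8L),
  OBP_DEVIANT4 = c(49L, 3L, 40L, 21L, 8L),
  OBP_PLUSC = c(30L, 3L, 43L, 24L, 9L, 8L, 0L, 9L),
  CSP = c(6L, 18L, 2L)
)

.accession_spec <- function(plan, motifs) {
  switch(plan,
    OBP_CLASSIC = motifs$OBP_CLASSIC,
    OBP_PLUSC = motifs$OBP_PLUSC,
    CSP = motifs$CSP_RESULTS,
    OBP_DEVIANT1 = parse_motif("C-x(25)-C-x(3)-C-x(47)-C-x(9)-C-x(8)-C",
                               "OBP_DEVIANT1"),
    OBP_DEVIANT4 = parse_motif("C-x(49)-C-x(3)-C-x(40)-C-x(21)-C-x(8)-C",
                               "OBP_DEVIANT4"),
    stop("unknown plan ", plan))
}

#' Synthetic stand-ins for the deposited chemosensory gene records
#'
#' Builds, deterministically from `seed`, one transcript per catalogued
#' gene whose longest-ORF protein has the record's published precursor
#' length, completeness flag and cysteine-spacing architecture. These are
#' synthetic surrogates for offline testing -- see
#' `scripts/fetch_accessions.R` for retrieving the real deposited mRNAs.
#'
#' @param seed Integer seed.
#' @return List with `transcripts` (data frame `id` = accession, `seq`,
#'   `description` = gene name) and `metadata` (the catalogue plus a
#'   `family` column, OBP or CSP).
#' @export
synthetic_accession_set <- function(seed = 1L) {
  cat <- .accession_catalogue()
  motifs <- motif_library()
  with_seed(seed + SEED_OFFSETS[["accessions"]], {
    tx <- vector("list", nrow(cat))
    for (i in seq_len(nrow(cat))) {
      plan <- cat$plan[i]
      spec <- .accession_spec(plan, motifs)
      gaps <- .accession_gaps[[plan]]
      motif_span <- length(spec$anchors) + sum(gaps)
      # protein length budget: optional leading M + flanks + motif span
      core_len <- cat$length[i] - as.integer(cat$complete[i])
      f3_min <- max(spec$min_tail, 10L)
      f5_max <- core_len - motif_span - f3_min
      if (f5_max < 0L) stop("length budget too small for ", cat$gene[i])
      f5 <- min(sample(15L:25L, 1L), f5_max)
      f3 <- core_len - motif_span - f5
      planted <- plant_motif(spec, gaps, flanks = c(f5, f3))
      built <- .build_transcript(planted$protein, cat$complete[i],
                                 min_aa = 80L)
      tx[[i]] <- data.frame(id = cat$accession[i], seq = built$seq,
                            description = cat$gene[i],
                            stringsAsFactors = FALSE)
    }
    meta <- cat
    meta$family <- ifelse(grepl("^SaveOBP", cat$gene), "OBP", "CSP")
    list(transcripts = do.call(rbind, tx), metadata = meta)
  })
}
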