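#!/usr/bin/env Rscript
# Fetches the deposited mRNA sequences KU140605-KU140622 from NCBI (network
# required) and writes them as a single nucleotide FASTA. The test-suite and
# acceptance script use synthetic stand-ins (see ?synthetic_accession_set);
# this helper retrieves the real records for anyone who wants to run the
# mining pipeline on them:
#   Rscript scripts/fetch_accessions.R [out.fasta]

args <- commandArgs(trailingOnly = TRUE)
out <- if (length(args) >= 1L) args[1L] else "accessions_KU140605-KU140622.fasta"

accs <- sprintf("KU1406%02d", 5:22)
base <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi"
url <- paste0(base, "?db=nuccore&id=", paste(accs, collapse = ","),
              "&rettype=fasta&retmode=text")
message("fetching ", length(accs), " records from NCBI ...")
download.file(url, out, quiet = TRUE)
n <- sum(startsWith(readLines(out), ">"))
if (n != length(accs)) {
  stop("expected ", length(accs), " records, got ", n)
}
message("wrote ", out)
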