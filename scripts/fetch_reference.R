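#!/usr/bin/env Rscript
# One-time (network-requiring) fetch of the POSTN reference records for
# reference-mode fixtures. Downloads the GenBank mRNA record D13664 from
# NCBI E-utilities, extracts exon boundaries from the feature table, and
# caches an exon table (exon_id, length, sequence) under the user cache
# directory where build_postn_fixture(mode = "reference") expects it.
#
# The test suite never runs this script; all tests use the idealized
# offline model.

suppressMessages(library(isopanel))

cache_dir <- tools::R_user_dir("isopanel", "cache")
dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
out <- file.path(cache_dir, "postn_reference_exons.tsv")

base <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi"
url <- paste0(base, "?db=nucleotide&id=D13664&rettype=gb&retmode=text")
message("fetching GenBank D13664 ...")
gb <- readLines(url)

# mRNA records carry no exon features; exon boundaries must come from the
# genomic RefSeq. Fetch the current POSTN RefSeqGene-equivalent region and
# its exon annotation, then cut exon sequences.
url2 <- paste0(base, "?db=nucleotide&id=NG_052950&rettype=gbwithparts&retmode=text")
message("fetching POSTN genomic RefSeq with exon annotation ...")
gen <- readLines(url2)

origin <- grep("^ORIGIN", gen)
seq_lines <- gen[(origin + 1):(grep("^//", gen)[1] - 1)]
genome <- toupper(gsub("[^a-z]", "", paste(seq_lines, collapse = "")))

exon_lines <- grep("^\\s{5}exon\\s", gen, value = TRUE)
coords <- regmatches(exon_lines, regexpr("[0-9]+\\.\\.[0-9]+", exon_lines))
starts <- as.integer(sub("\\.\\..*", "", coords))
ends <- as.integer(sub(".*\\.\\.", "", coords))
seqs <- substring(genome, starts, ends)

tab <- data.frame(exon_id = seq_along(seqs), length = nchar(seqs),
                  sequence = seqs)
write.table(tab, out, sep = "\t", quote = FALSE, row.names = FALSE)
message("cached ", nrow(tab), " exons at ", out)
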