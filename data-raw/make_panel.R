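# One-off generator for the packaged synthetic reference panel.
# Run once; outputs are committed as plain-text FASTA/JSON under inst/extdata/panel.
set.seed(20150911L)

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

# Synthetic COI barcode reference, 658 bp, thymine at the diagnostic site
# (position 300 of the fragment; stands in for mitogenome position 2382).
coi <- rand_dna(658)
substr(coi, 300, 300) <- "T"
# keep the reference free of the BglII motif so it can double as a digest fixture
while (grepl("AGATCT", coi, fixed = TRUE)) {
  coi <- rand_dna(658)
  substr(coi, 300, 300) <- "T"
}

# Four synthetic COI-COII spacer exemplars: common ancestor + ~12% divergence each.
anc <- rand_dna(220)
mutate <- function(s, n) {
  pos <- sample(nchar(s), n)
  v <- strsplit(s, "")[[1]]
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  paste(v, collapse = "")
}
ex <- list(A = mutate(anc, 26), C = mutate(anc, 26), M = mutate(anc, 26), O = mutate(anc, 26))
d <- outer(names(ex), names(ex), Vectorize(function(i, j) c(utils::adist(ex[[i]], ex[[j]]))))
cat("pairwise exemplar distances:\n"); print(d)
stopifnot(min(d[upper.tri(d)]) >= 30)

dir.create("inst/extdata/panel", recursive = TRUE, showWarnings = FALSE)
writeLines(c(">COI_reference_synthetic stand-in barcode fragment; diagnostic site at 300",
             coi), "inst/extdata/panel/coi_reference_synthetic.fasta")
writeLines(unlist(lapply(names(ex), function(l) {
  c(sprintf(">%s synthetic COI-COII spacer exemplar (non-empirical stand-in)", l), ex[[l]])
})), "inst/extdata/panel/spacer_exemplars_synthetic.fasta")
jsonlite::write_json(list(
  coi_reference_fasta = "coi_reference_synthetic.fasta",
  spacer_fasta = "spacer_exemplars_synthetic.fasta",
  coi_diagnostic_position = 300L,
  coi_diagnostic_note = paste("Fragment coordinate of the diagnostic C/T site;",
                              "maps to position 2382 in mitogenome reference numbering.",
                              "C = African, T = European."),
  restriction_motif = "AGATCT",
  cut_offset = 1L,
  min_visible_bp = 50L,
  synthetic = TRUE
), "inst/extdata/panel/panel.json", auto_unbox = TRUE, pretty = TRUE)
cat("done\n")
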