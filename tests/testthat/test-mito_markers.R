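test_that("digest splits at every motif occurrence with configurable cut offset", {
  set.seed(101)
  # no occurrence: one fragment spanning the whole sequence
  s485 <- local({
    s <- rand_dna(485)
    while (grepl("AGATCT", s, fixed = TRUE)) s <- rand_dna(485)
    s
  })
  expect_equal(digest(s485), 485L)
  # 100 clean bases + motif + 94 clean bases, offset 1 -> fragments 101 and 99
  left <- local({
    s <- rand_dna(100)
    while (grepl("AGATCT", paste0(s, "AGATC"), fixed = TRUE)) s <- rand_dna(100)
    s
  })
  right <- local({
    s <- rand_dna(94)
    while (grepl("AGATCT", paste0("GATCT", s), fixed = TRUE)) s <- rand_dna(94)
    s
  })
  seq1 <- paste0(left, "AGATCT", right)
  expect_equal(digest(seq1, min_visible_bp = 0), c(101L, 99L))
  # the visibility floor suppresses both fragments
  expect_equal(digest(seq1, min_visible_bp = 150), integer(0))
  # cut offset moves the boundary, not the band count
  expect_equal(digest(seq1, min_visible_bp = 0, cut_offset = 3), c(103L, 97L))
  expect_equal(sum(digest(seq1, min_visible_bp = 0, cut_offset = 3)), 200L)
})

test_that("digest agrees with the brute-force splitter on random sequences", {
  set.seed(202)
  for (i in 1:300) {
    len <- sample(50:2000, 1)
    s <- rand_dna(len)
    motif <- sample(c("AGATCT", "GAAT", "ACGT"), 1)
    off <- sample(seq_len(nchar(motif)), 1)
    mine <- digest(s, motif, min_visible_bp = 0, cut_offset = off)
    oracle <- brute_digest(s, motif, min_visible_bp = 0, cut_offset = off)
    expect_equal(mine, as.integer(oracle))
    expect_equal(sum(mine), len)  # conservation
  }
})

test_that("digest validates inputs and treats N conservatively", {
  expect_error(digest(""), "non-empty")
  expect_error(digest("ACGT", motif = "AGNTCT"), "ACGT")
  # N never matches the motif, so an uncertain site cannot create a cut
  expect_equal(digest("AAAANGATCTAAAA", motif = "AGATCT"), 14L)
  expect_equal(digest("AAAAAGATCTAAAA", motif = "AGATCT", min_visible_bp = 0),
               c(5L, 9L))
})

test_that("rflp_mitotype scores one band African, two European, else indeterminate", {
  panel <- local_panel()
  set.seed(7)
  afr <- make_marker_sequences("african", panel, seed = 7)$cytb
  eur <- make_marker_sequences("european", panel, seed = 7)$cytb
  ca <- rflp_mitotype(afr, panel)
  ce <- rflp_mitotype(eur, panel)
  expect_equal(ca$call, "african")
  expect_true(ca$confident)
  expect_match(ca$evidence, "bands=\\[485\\]")
  expect_equal(ce$call, "european")
  # two motif occurrences -> three bands -> indeterminate
  tri <- paste0(substr(afr, 1, 150), "AGATCT", substr(afr, 151, 300),
                "AGATCT", substr(afr, 301, 485))
  ci <- rflp_mitotype(tri, panel)
  expect_equal(ci$call, "indeterminate")
  expect_false(ci$confident)
  expect_warning(rflp_mitotype(strrep("A", 50), panel), "plausible")
})

test_that("coi_snp_call reads the diagnostic base through alignment", {
  panel <- local_panel()
  pos <- panel$coi_diagnostic_position
  ref <- panel$coi_reference
  # the packaged reference itself carries T -> european
  self <- coi_snp_call(ref, panel)
  expect_equal(self$call, "european")
  expect_true(self$confident)
  # single diagnostic substitution to C -> african
  afr <- ref
  substr(afr, pos, pos) <- "C"
  expect_equal(coi_snp_call(afr, panel)$call, "african")
  # any other base -> indeterminate
  amb <- ref
  substr(amb, pos, pos) <- "G"
  expect_equal(coi_snp_call(amb, panel)$call, "indeterminate")
  # fragment starting downstream of the site still maps correctly
  frag <- substr(ref, pos - 150, nchar(ref))
  expect_equal(coi_snp_call(frag, panel)$call, "european")
  # truncated upstream of the site -> position not covered
  trunc <- substr(ref, 1, pos - 10)
  tc <- coi_snp_call(trunc, panel)
  expect_equal(tc$call, "indeterminate")
  expect_match(tc$evidence, "not covered")
  # unrelated sequence fails the identity threshold
  set.seed(5)
  junk <- rand_dna(650)
  jc <- coi_snp_call(junk, panel)
  expect_equal(jc$call, "indeterminate")
  expect_false(jc$confident)
})

test_that("spacer_lineage assigns the nearest exemplar and reports distances", {
  panel <- local_panel()
  # exact copies
  for (lg in names(panel$spacer_exemplars)) {
    cl <- spacer_lineage(panel$spacer_exemplars[[lg]], panel)
    expect_equal(cl$call, paste0("lineage_", lg))
    expect_true(cl$confident)
    expect_match(cl$evidence, paste0(lg, "=0.0000"))
  }
})

test_that("spacer_lineage tolerates substitutions up to half the exemplar gap", {
  panel <- local_panel()
  exem <- panel$spacer_exemplars
  # minimum pairwise exemplar distance, by independent Levenshtein oracle
  dmin <- min(utils::adist(exem)[upper.tri(diag(length(exem)))])
  m <- floor((dmin - 1) / 2)  # strictly below half the minimum gap
  set.seed(31)
  for (lg in c("A", "M")) {
    s <- exem[[lg]]
    v <- strsplit(s, "")[[1]]
    pos <- sample(length(v), m)
    for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
    mut <- paste(v, collapse = "")
    cl <- spacer_lineage(mut, panel)
    expect_equal(cl$call, paste0("lineage_", lg))
  }
  # at a light mutation load the normalized distance equals the Levenshtein
  # oracle exactly (no gaps enter the optimal alignment)
  set.seed(32)
  s <- exem[["O"]]
  v <- strsplit(s, "")[[1]]
  for (p in sample(length(v), 3)) {
    v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  }
  mut <- paste(v, collapse = "")
  cl <- spacer_lineage(mut, panel)
  expect_equal(cl$call, "lineage_O")
  d_oracle <- c(utils::adist(mut, s)) / nchar(s)
  hit <- regmatches(cl$evidence, regexpr("O=[0-9.]+", cl$evidence))
  expect_equal(as.numeric(sub("^.=", "", hit)), round(d_oracle, 4),
               tolerance = 1e-4)
})

test_that("spacer_lineage returns indeterminate on a tie", {
  panel <- reference_panel(
    coi_reference = strrep("ACGT", 40), coi_diagnostic_position = 10,
    spacer_exemplars = c(X = paste0(strrep("A", 60), "C"),
                         Y = paste0(strrep("A", 60), "G"))
  )
  # query equidistant (1 edit) from both exemplars
  cl <- spacer_lineage(paste0(strrep("A", 60), "T"), panel)
  expect_equal(cl$call, "indeterminate")
  expect_false(cl$confident)
})

test_that("marker_call enforces its invariants", {
  expect_error(marker_call("coi_snp", "indeterminate", "x", TRUE), "confident")
  expect_error(marker_call("coi_snp", "african", "", TRUE), "evidence")
  expect_silent(marker_call("coi_snp", "indeterminate", "", FALSE))
})

test_that("generated specimens give fully concordant assays with zero mutations", {
  panel <- local_panel()
  n <- 40
  set.seed(13)
  mito <- rep(c("african", "european"), c(24, 16))
  seqs <- lapply(seq_len(n), function(i) {
    make_marker_sequences(mito[i], panel, seed = 1000 + i)
  })
  calls <- call_markers(tibble::tibble(
    specimen_id = rep(sprintf("b%02d", 1:n), each = 3),
    marker = rep(c("cytb", "COI", "spacer"), n),
    sequence = unlist(seqs, use.names = FALSE)
  ), panel)
  # each assay recovers the generating mitotype for every bee
  calls$class <- ifelse(calls$call %in% c("african", "lineage_A"),
                        "african", "european")
  expect_true(all(calls$confident))
  expect_equal(calls$class, rep(mito, each = 3))
  conc <- concordance_table(calls)
  expect_true(all(conc$concordant))
  expect_equal(unname(conc$tables[["coi_snp:cytb_rflp"]]["african", "african"]), 24)
})

test_that("concordance_table flags a single discordant specimen and rejects bad input", {
  calls <- tibble::tibble(
    specimen_id = rep(sprintf("b%d", 1:3), each = 2),
    marker = rep(c("cytb_rflp", "coi_snp"), 3),
    call = c("african", "african", "european", "european", "african", "african"),
    evidence = "x", confident = TRUE
  )
  expect_true(all(concordance_table(calls)$concordant))
  calls$call[6] <- "european"  # b3 discordant
  expect_false(any(concordance_table(calls)$concordant))
  expect_error(concordance_table(calls[0, ]), "no marker calls")
  expect_error(concordance_table(calls[1, ]), "at least two")
})
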