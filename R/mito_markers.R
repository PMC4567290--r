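#' Construct a marker call
#'
#' Result of one mitochondrial assay on one specimen. An `indeterminate` call
#' is never confident, and every confident call carries non-empty evidence
#' (band lengths, observed base, or nearest-reference distances).
#'
#' @param marker `"cytb_rflp"`, `"coi_snp"` or `"spacer_lineage"`.
#' @param call `"african"`, `"european"`, a `"lineage_<label>"` value, or
#'   `"indeterminate"`.
#' @param evidence Human-readable evidence string.
#' @param confident Logical.
#' @return Object of class `marker_call` (a named list).
#' @export
marker_call <- function(marker, call, evidence, confident) {
  stopifnot(marker %in% c("cytb_rflp", "coi_snp", "spacer_lineage"))
  if (call == "indeterminate" && confident) {
    stop("an indeterminate call cannot be confident", call. = FALSE)
  }
  if (confident && !nzchar(evidence)) {
    stop("a confident call requires non-empty evidence", call. = FALSE)
  }
  structure(list(marker = marker, call = call, evidence = evidence,
                 confident = confident), class = "marker_call")
}

#' @export
print.marker_call <- function(x, ...) {
  cat(sprintf("<marker_call> %s: %s%s  [%s]\n", x$marker, x$call,
              if (x$confident) "" else " (not confident)", x$evidence))
  invisible(x)
}

#' @export
as.data.frame.marker_call <- function(x, ...) {
  data.frame(marker = x$marker, call = x$call, evidence = x$evidence,
             confident = x$confident, stringsAsFactors = FALSE)
}

.validate_seq <- function(seq, what = "sequence") {
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    stop(what, " must be a single non-empty string", call. = FALSE)
  }
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) {
    stop(what, " may contain only A, C, G, T, N", call. = FALSE)
  }
  seq
}

#' In-silico restriction digest
#'
#' Cuts a sequence at every exact occurrence of the recognition motif and
#' returns the lengths of the resulting fragments, mimicking a gel lane: only
#' fragments of at least `min_visible_bp` are reported (a tiny terminal
#' fragment runs off the gel). The cut falls after base `cut_offset` of the
#' motif (1 for BglII: A^GATCT). Ambiguous bases (N) in the sequence never
#' match the motif, so an uncertain site cannot create a cut.
#'
#' @param seq Nucleotide string (ACGTN, case-insensitive).
#' @param motif Recognition site, ACGT only (no ambiguity codes).
#' @param min_visible_bp Fragments shorter than this are suppressed; with 0
#'   the fragment lengths always sum to `nchar(seq)`.
#' @param cut_offset Cut after this base of the motif.
#' @return Integer vector of visible fragment lengths in positional order.
#' @export
#' @examples
#' digest(paste0(strrep("A", 100), "AGATCT", strrep("C", 94)), min_visible_bp = 0)
digest <- function(seq, motif = "AGATCT", min_visible_bp = 0L, cut_offset = 1L) {
  seq <- .validate_seq(seq)
  motif <- toupper(motif)
  if (!nzchar(motif) || grepl("[^ACGT]", motif)) {
    stop("motif must be a non-empty ACGT-only string", call. = FALSE)
  }
  cut_offset <- as.integer(cut_offset)
  len <- nchar(seq)
  hits <- Biostrings::matchPattern(motif, Biostrings::DNAString(seq),
                                   fixed = TRUE)
  cuts <- Biostrings::start(hits) + cut_offset - 1L
  cuts <- sort(unique(cuts[cuts >= 1L & cuts < len]))
  frags <- diff(c(0L, cuts, len))
  as.integer(frags[frags >= min_visible_bp])
}

#' Cytochrome b BglII restriction mitotype
#'
#' In-silico analogue of the classic gel assay: the cytochrome b amplicon of
#' African-lineage mitochondria lacks the BglII site and yields one band,
#' while European/Middle Eastern mitochondria carry the site and yield two.
#' Any other visible band count is scored indeterminate.
#'
#' @param seq Cytochrome b amplicon sequence (plausibility bounds 100-2000 bp,
#'   warning outside).
#' @param panel A [reference_panel()] supplying motif, cut offset and the
#'   visibility floor.
#' @param min_visible_bp Override of the panel's visibility floor.
#' @return A [marker_call()] with `marker = "cytb_rflp"`.
#' @export
rflp_mitotype <- function(seq, panel = default_panel(),
                          min_visible_bp = panel$min_visible_bp) {
  seq <- .validate_seq(seq, "amplicon")
  if (nchar(seq) < 100L || nchar(seq) > 2000L) {
    warning(sprintf("amplicon length %d bp outside plausible range 100-2000",
                    nchar(seq)), call. = FALSE)
  }
  bands <- digest(seq, panel$restriction_motif, min_visible_bp,
                  panel$cut_offset)
  evidence <- sprintf("bands=[%s]", paste(bands, collapse = ","))
  if (length(bands) == 1L) {
    marker_call("cytb_rflp", "african", evidence, TRUE)
  } else if (length(bands) == 2L) {
    marker_call("cytb_rflp", "european", evidence, TRUE)
  } else {
    marker_call("cytb_rflp", "indeterminate", evidence, FALSE)
  }
}

# Align a query to the panel COI reference and read the base opposite the
# diagnostic coordinate. Returns list(base, identity, covered).
.read_diagnostic_base <- function(barcode, panel) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(barcode),
    subject = Biostrings::DNAString(panel$coi_reference),
    type = "global-local", substitutionMatrix = mat,
    gapOpening = 5, gapExtension = 2
  )
  identity <- Biostrings::pid(aln)
  pos <- panel$coi_diagnostic_position
  s_start <- Biostrings::start(Biostrings::subject(aln))
  s_end <- Biostrings::end(Biostrings::subject(aln))
  if (pos < s_start || pos > s_end) {
    return(list(base = NA_character_, identity = identity, covered = FALSE))
  }
  p_chars <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s_chars <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  s_pos <- s_start - 1L
  base <- NA_character_
  for (i in seq_along(s_chars)) {
    if (s_chars[i] != "-") {
      s_pos <- s_pos + 1L
      if (s_pos == pos) {
        base <- p_chars[i]
        break
      }
    }
  }
  list(base = base, identity = identity, covered = TRUE)
}

#' Diagnostic COI barcode SNP call
#'
#' Reads the single diagnostic site in the COI DNA barcode that separates
#' African from non-African mitochondrial lineages (mitogenome reference
#' position 2382; annotated on the panel's reference fragment). The query is
#' pairwise-aligned to the reference (query-global within reference-local;
#' match 2 / mismatch -3, gap open 5 / extend 2) and the query base opposite
#' the diagnostic coordinate is read: cytosine scores African, thymine
#' European. A gap, another base, a query not covering the site, or alignment
#' identity below `min_identity` yields an indeterminate call rather than an
#' error.
#'
#' @param barcode COI barcode sequence (typically ~650 bp; warning below
#'   100 bp).
#' @param panel A [reference_panel()].
#' @param min_identity Minimum percent-identity (0-1 scale) of the alignment
#'   for a confident call; below this the record is unlikely to be honey-bee
#'   COI at all.
#' @return A [marker_call()] with `marker = "coi_snp"`.
#' @export
coi_snp_call <- function(barcode, panel = default_panel(), min_identity = 0.9) {
  barcode <- .validate_seq(barcode, "barcode")
  if (nchar(barcode) < 100L) {
    warning("barcode shorter than 100 bp", call. = FALSE)
  }
  res <- .read_diagnostic_base(barcode, panel)
  pos <- panel$coi_diagnostic_position
  if (!res$covered) {
    return(marker_call("coi_snp", "indeterminate",
                       sprintf("position %d not covered by alignment", pos),
                       FALSE))
  }
  evidence <- sprintf("base=%s at reference position %d; identity=%.1f%%",
                      res$base, pos, res$identity)
  if (res$identity < 100 * min_identity) {
    return(marker_call("coi_snp", "indeterminate",
                       paste0(evidence, " (below identity threshold)"), FALSE))
  }
  if (is.na(res$base) || res$base == "-") {
    marker_call("coi_snp", "indeterminate",
                sprintf("gap at reference position %d", pos), FALSE)
  } else if (res$base == "C") {
    marker_call("coi_snp", "african", evidence, TRUE)
  } else if (res$base == "T") {
    marker_call("coi_snp", "european", evidence, TRUE)
  } else {
    marker_call("coi_snp", "indeterminate", evidence, FALSE)
  }
}

#' COI-COII spacer lineage assignment
#'
#' Assigns a spacer sequence to the mitochondrial lineage (A = Africa,
#' C = Carniolan, M = west European, O = Oriental, by convention) of its
#' nearest reference exemplar. Distance is the normalized edit distance of a
#' global pairwise alignment (edits / alignment length). This deterministic
#' nearest-reference rule stands in for full phylogenetic placement, which is
#' adequate at exemplar level when the exemplars are well separated; a tie for
#' the minimum yields an indeterminate call.
#'
#' @param seq Spacer sequence (warning below 50 bp).
#' @param panel A [reference_panel()] with named exemplars.
#' @return A [marker_call()] with `marker = "spacer_lineage"` and call
#'   `lineage_<label>` of the unique nearest exemplar.
#' @export
spacer_lineage <- function(seq, panel = default_panel()) {
  seq <- .validate_seq(seq, "spacer")
  if (nchar(seq) < 50L) warning("spacer shorter than 50 bp", call. = FALSE)
  d <- vapply(panel$spacer_exemplars, function(ref) {
    .alignment_distance(seq, ref)
  }, numeric(1))
  evidence <- paste(sprintf("%s=%.4f", names(d), d), collapse = ", ")
  ord <- order(d)
  if (length(d) > 1L && abs(d[ord[1]] - d[ord[2]]) < 1e-12) {
    marker_call("spacer_lineage", "indeterminate",
                paste0("tie for nearest exemplar: ", evidence), FALSE)
  } else {
    marker_call("spacer_lineage", paste0("lineage_", names(d)[ord[1]]),
                evidence, TRUE)
  }
}

# Normalized edit distance from a global alignment (Levenshtein-style
# scoring: match 1, mismatch -1, unit gap cost).
.alignment_distance <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(a), subject = Biostrings::DNAString(b),
    type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 1
  )
  Biostrings::nedit(aln) / nchar(as.character(Biostrings::alignedPattern(aln)))
}

#' Call all available markers for a table of sequences
#'
#' Applies the three assays to whichever of the marker sequences (`cytb`,
#' `COI`, `spacer`) each specimen carries.
#'
#' @param sequences Tibble with columns `specimen_id`, `marker` (one of
#'   `cytb`, `COI`, `spacer`) and `sequence`; or the output of
#'   [sample_population()] (its `sequences` list-column is unnested).
#' @param panel A [reference_panel()].
#' @return Tibble with `specimen_id`, `marker`, `call`, `evidence`,
#'   `confident`.
#' @export
call_markers <- function(sequences, panel = default_panel()) {
  if ("sequences" %in% names(sequences)) {
    sequences <- unnest_sequences(sequences)
  }
  need <- c("specimen_id", "marker", "sequence")
  miss <- setdiff(need, names(sequences))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(sequences)), function(i) {
    mk <- sequences$marker[i]
    sq <- sequences$sequence[i]
    cl <- switch(mk,
      cytb = rflp_mitotype(sq, panel),
      COI = coi_snp_call(sq, panel),
      spacer = spacer_lineage(sq, panel),
      stop("unknown marker: ", mk, call. = FALSE)
    )
    cbind(specimen_id = sequences$specimen_id[i], as.data.frame(cl))
  })
  tibble::as_tibble(do.call(rbind, rows))
}

#' Flatten the sequences list-column of a simulated population
#'
#' @param population Output of [sample_population()].
#' @return Tibble with `specimen_id`, `marker`, `sequence`.
#' @export
unnest_sequences <- function(population) {
  stopifnot("sequences" %in% names(population))
  rows <- lapply(seq_len(nrow(population)), function(i) {
    sq <- population$sequences[[i]]
    tibble::tibble(specimen_id = population$specimen_id[i],
                   marker = names(sq), sequence = unlist(sq, use.names = FALSE))
  })
  dplyr::bind_rows(rows)
}

# Collapse any marker call to the binary African/European mitotype class.
.call_class <- function(call) {
  ifelse(call %in% c("african", "lineage_A"), "african",
         ifelse(call == "european" | grepl("^lineage_", call), "european",
                NA_character_))
}

#' Marker concordance cross-tabulation
#'
#' Cross-tabulates the African/European class of every pair of markers scored
#' on the same specimens (spacer lineages collapse to African for lineage A,
#' European otherwise). A pair is flagged perfectly concordant when its
#' off-diagonal cells are empty — the in-silico analogue of perfect linkage
#' between the restriction site, the barcode SNP and the spacer lineage.
#'
#' @param calls Tibble of calls as from [call_markers()]; only confident calls
#'   are used, and every specimen must retain at least two markers.
#' @return Object of class `concordance` holding the per-pair 2x2 tables,
#'   per-pair concordance flags, per-marker class counts and the spacer
#'   lineage breakdown.
#' @export
concordance_table <- function(calls) {
  if (nrow(calls) == 0L) stop("no marker calls supplied", call. = FALSE)
  calls <- calls[calls$confident, , drop = FALSE]
  calls$class <- .call_class(calls$call)
  calls <- calls[!is.na(calls$class), , drop = FALSE]
  per_spec <- table(calls$specimen_id)
  if (nrow(calls) == 0L || any(per_spec < 2L)) {
    stop("every specimen needs confident calls for at least two markers",
         call. = FALSE)
  }
  markers <- sort(unique(calls$marker))
  if (length(markers) < 2L) {
    stop("fewer than two markers available", call. = FALSE)
  }
  pairs <- utils::combn(markers, 2L, simplify = FALSE)
  lv <- c("african", "european")
  tables <- list()
  concordant <- logical(0)
  for (pr in pairs) {
    a <- calls[calls$marker == pr[1], c("specimen_id", "class")]
    b <- calls[calls$marker == pr[2], c("specimen_id", "class")]
    m <- merge(a, b, by = "specimen_id")
    tab <- table(factor(m$class.x, lv), factor(m$class.y, lv),
                 dnn = c(pr[1], pr[2]))
    key <- paste(pr, collapse = ":")
    tables[[key]] <- tab
    concordant[key] <- tab["african", "european"] == 0L &&
      tab["european", "african"] == 0L
  }
  lineages <- calls$call[calls$marker == "spacer_lineage"]
  structure(list(
    tables = tables,
    concordant = concordant,
    class_counts = table(calls$marker, calls$class),
    lineage_counts = if (length(lineages)) table(sub("^lineage_", "", lineages)),
    n_specimens = length(per_spec)
  ), class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("<concordance> %d specimens, %d marker pair(s)\n",
              x$n_specimens, length(x$tables)))
  for (key in names(x$tables)) {
    cat(sprintf("\n%s — %s\n", key,
                if (x$concordant[[key]]) "perfectly concordant" else "DISCORDANT"))
    print(x$tables[[key]])
  }
  if (!is.null(x$lineage_counts)) {
    cat("\nspacer lineages:\n")
    print(x$lineage_counts)
  }
  invisible(x)
}
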