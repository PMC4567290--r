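#' Reference panel for the mitochondrial assays
#'
#' Bundles everything the three marker assays need: a COI barcode reference
#' with the annotated diagnostic C/T coordinate, one exemplar COI-COII spacer
#' sequence per mitochondrial lineage, and the restriction motif of the typing
#' enzyme (BglII, `AGATCT`, cutting after the first base: `A^GATCT`).
#'
#' The diagnostic coordinate is stored as an annotation on the packaged
#' reference fragment rather than as a hard-coded barcode offset; queries are
#' mapped onto it by pairwise alignment, so barcode fragments starting at any
#' offset are handled.
#'
#' @param coi_reference COI reference sequence (character, ACGT).
#' @param coi_diagnostic_position 1-based coordinate of the diagnostic C/T site
#'   within `coi_reference`.
#' @param spacer_exemplars Named character vector of spacer sequences, one per
#'   lineage label (conventionally A, C, M, O; arbitrary labels accepted).
#' @param restriction_motif Recognition site of the typing enzyme (ACGT only,
#'   length >= 4).
#' @param cut_offset Cut position within the motif: the enzyme cuts after base
#'   `cut_offset` (1 for BglII's A^GATCT). Band counts are insensitive to this;
#'   fragment lengths are not.
#' @param min_visible_bp Gel-visibility floor: fragments shorter than this are
#'   not counted as bands.
#' @return An object of class `reference_panel`.
#' @seealso [default_panel()], [read_panel()]
#' @export
reference_panel <- function(coi_reference, coi_diagnostic_position,
                            spacer_exemplars, restriction_motif = "AGATCT",
                            cut_offset = 1L, min_visible_bp = 50L) {
  coi_reference <- toupper(coi_reference)
  spacer_exemplars <- toupper(spacer_exemplars)
  stopifnot(is.character(coi_reference), length(coi_reference) == 1L)
  pos <- as.integer(coi_diagnostic_position)
  if (is.na(pos) || pos < 1L || pos > nchar(coi_reference)) {
    stop("diagnostic coordinate must lie within the COI reference", call. = FALSE)
  }
  if (is.null(names(spacer_exemplars)) || anyNA(names(spacer_exemplars)) ||
      any(names(spacer_exemplars) == "")) {
    stop("spacer exemplars must be named by lineage", call. = FALSE)
  }
  if (anyDuplicated(spacer_exemplars)) {
    stop("spacer exemplars must be pairwise distinct", call. = FALSE)
  }
  if (nchar(restriction_motif) < 4L ||
      grepl("[^ACGT]", toupper(restriction_motif))) {
    stop("restriction motif must be >= 4 bp of ACGT only", call. = FALSE)
  }
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0L || cut_offset > nchar(restriction_motif)) {
    stop("cut_offset must lie within the motif", call. = FALSE)
  }
  structure(
    list(
      coi_reference = coi_reference,
      coi_diagnostic_position = pos,
      spacer_exemplars = spacer_exemplars,
      restriction_motif = toupper(restriction_motif),
      cut_offset = cut_offset,
      min_visible_bp = as.integer(min_visible_bp)
    ),
    class = "reference_panel"
  )
}

#' @export
print.reference_panel <- function(x, ...) {
  cat("<reference_panel>\n")
  cat(sprintf("  COI reference: %d bp, diagnostic site at %d (ref base %s)\n",
              nchar(x$coi_reference), x$coi_diagnostic_position,
              substr(x$coi_reference, x$coi_diagnostic_position,
                     x$coi_diagnostic_position)))
  cat(sprintf("  spacer exemplars: %s\n",
              paste(sprintf("%s (%d bp)", names(x$spacer_exemplars),
                            nchar(x$spacer_exemplars)), collapse = ", ")))
  cat(sprintf("  restriction motif: %s (cut after base %d), min visible band %d bp\n",
              x$restriction_motif, x$cut_offset, x$min_visible_bp))
  invisible(x)
}

#' Read a reference panel from a directory
#'
#' The directory must hold a `panel.json` annotation naming the COI reference
#' FASTA, the spacer exemplar FASTA, the diagnostic coordinate, the restriction
#' motif, the cut offset and the visibility floor. Users reproducing published
#' mitotype assignments should point this at their own directory of real
#' reference haplotypes; the packaged panel is a synthetic stand-in.
#'
#' @param dir Directory containing `panel.json` and the FASTA files it names.
#' @return A [reference_panel()].
#' @export
read_panel <- function(dir) {
  ann_path <- file.path(dir, "panel.json")
  if (!file.exists(ann_path)) {
    stop("no panel.json found in ", dir, call. = FALSE)
  }
  ann <- jsonlite::read_json(ann_path, simplifyVector = TRUE)
  coi <- read_fasta(file.path(dir, ann$coi_reference_fasta))
  sp <- read_fasta(file.path(dir, ann$spacer_fasta))
  reference_panel(
    coi_reference = coi$sequence[[1]],
    coi_diagnostic_position = ann$coi_diagnostic_position,
    spacer_exemplars = stats::setNames(sp$sequence, sp$id),
    restriction_motif = ann$restriction_motif,
    cut_offset = ann$cut_offset %||% 1L,
    min_visible_bp = ann$min_visible_bp %||% 50L
  )
}

#' Packaged synthetic reference panel
#'
#' Loads the panel shipped under `inst/extdata/panel/`. Its sequences are
#' clearly labelled synthetic stand-ins generated with a fixed seed: they have
#' the right structure (a 658 bp motif-free COI fragment with T at the
#' diagnostic site; four well-separated spacer exemplars labelled A, C, M, O)
#' but are not real haplotypes. Substitute a panel of real references via
#' [read_panel()] to type field material.
#'
#' @return A [reference_panel()].
#' @export
default_panel <- function() {
  read_panel(system.file("extdata", "panel", package = "afribee",
                         mustWork = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
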