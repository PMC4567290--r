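#' Read a worker morphometric measurement table
#'
#' Reads a delimited table of per-worker measurements with mandatory columns
#' `specimen_id`, `site_id`, `FWL`, `HWL`, `TL`, `FL` (forewing, hindwing,
#' tibia and femur lengths, all in millimetres). Extra columns are preserved
#' as metadata. The delimiter is sniffed from the header line (comma or tab
#' only); anything else must be passed explicitly.
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param delim Optional explicit delimiter; overrides sniffing.
#' @param skip_bad Drop rows with non-numeric measurements (with a warning)
#'   instead of failing. Default is fail-fast so downstream counts are
#'   reproducible.
#' @return A tibble, one row per worker, in input row order. Measurement
#'   columns are numeric (mm).
#' @export
read_measurements <- function(path, delim = NULL, skip_bad = FALSE) {
  if (is.null(delim)) delim <- .sniff_delim(path)
  tbl <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  required <- c("specimen_id", "site_id", "FWL", "HWL", "TL", "FL")
  miss <- setdiff(required, names(tbl))
  if (length(miss)) {
    stop("measurement table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  meas_cols <- c("FWL", "HWL", "TL", "FL")
  if (nrow(tbl) == 0L) {
    for (cl in meas_cols) tbl[[cl]] <- numeric(0)
    return(tbl)
  }
  parsed <- lapply(tbl[meas_cols], function(x) suppressWarnings(as.numeric(x)))
  bad_rows <- sort(unique(unlist(lapply(parsed, function(x) which(is.na(x))))))
  if (length(bad_rows)) {
    if (!skip_bad) {
      stop(sprintf("non-numeric measurement in data row(s): %s",
                   paste(bad_rows, collapse = ", ")), call. = FALSE)
    }
    warning(sprintf("dropping %d row(s) with non-numeric measurements: %s",
                    length(bad_rows), paste(bad_rows, collapse = ", ")),
            call. = FALSE)
  }
  tbl[meas_cols] <- parsed
  if (length(bad_rows) && skip_bad) tbl <- tbl[-bad_rows, ]
  if (anyDuplicated(tbl$specimen_id)) {
    warning("duplicated specimen_id values in measurement table", call. = FALSE)
  }
  tbl
}

.sniff_delim <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L) return(",")
  if (grepl("\t", header)) "\t" else ","
}

#' Write a measurement table
#'
#' Inverse of [read_measurements()]; values are written at full precision so a
#' read/write round trip is lossless.
#'
#' @param x Tibble as returned by [read_measurements()].
#' @param path Output path.
#' @param delim `,` or tab.
#' @export
write_measurements <- function(x, path, delim = ",") {
  readr::write_delim(x, path, delim = delim)
  invisible(path)
}

#' Read nucleotide sequences from FASTA
#'
#' Sequences are uppercased; record IDs are the first whitespace-delimited
#' token of each header. IUPAC ambiguity codes are accepted; anything else is
#' a format error naming the offending record.
#'
#' @param path FASTA file.
#' @return Tibble with columns `id` and `sequence`, in input order.
#' @export
read_fasta <- function(path) {
  # Biostrings silently drops invalid letters, so validate records first.
  .report_bad_fasta_record(path)
  set <- Biostrings::readDNAStringSet(path)
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[[`, character(1), 1L)
  tibble::tibble(id = ids,
                 sequence = toupper(unname(as.character(set))))
}

# Identify which record holds non-IUPAC characters so the error is actionable.
.report_bad_fasta_record <- function(path) {
  lines <- readLines(path, warn = FALSE)
  id <- NA_character_
  iupac <- "^[ACGTRYSWKMBDHVNUacgtryswkmbdhvnu.+*-]*$"
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      id <- strsplit(sub("^>", "", ln), "[ \t]+")[[1]][1]
    } else if (!grepl(iupac, ln)) {
      stop(sprintf("record '%s' contains non-IUPAC characters", id),
           call. = FALSE)
    }
  }
  invisible(NULL)
}

#' Write sequences to FASTA
#'
#' @param x Tibble with columns `id` and `sequence` (or a named character
#'   vector).
#' @param path Output path.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- tibble::tibble(id = names(x), sequence = unname(x))
  set <- Biostrings::DNAStringSet(x$sequence)
  names(set) <- x$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a BOLD-style TSV export of barcode records
#'
#' Reads a Barcode of Life Data System style tab-separated export and returns
#' reference specimens carrying a COI sequence and coordinates. Records
#' lacking a sequence or coordinates are flagged in the `flag` column, never
#' silently dropped; filtering is left to the caller.
#'
#' @param path TSV file with a header row.
#' @param columns Mapping from the roles `id`, `sequence`, `latitude`,
#'   `longitude` to column names in the file. Defaults follow classic BOLD
#'   exports (`processid`, `nucleotides`, `lat`, `lon`).
#' @return Tibble with `specimen_id`, `source = "reference"`, `latitude`,
#'   `longitude`, `COI` (uppercased, alignment gaps stripped) and `flag`
#'   (`"ok"`, `"no-sequence"` or `"no-coordinates"`).
#' @export
read_bold_tsv <- function(path,
                          columns = list(id = "processid",
                                         sequence = "nucleotides",
                                         latitude = "lat",
                                         longitude = "lon")) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  wanted <- unlist(columns)
  miss <- setdiff(wanted, names(tbl))
  if (length(miss)) {
    stop(sprintf("cannot map column(s) %s; available headers: %s",
                 paste(miss, collapse = ", "),
                 paste(names(tbl), collapse = ", ")), call. = FALSE)
  }
  seq <- toupper(gsub("[-. ]", "", tbl[[columns$sequence]]))
  seq[is.na(seq)] <- ""
  lat <- suppressWarnings(as.numeric(tbl[[columns$latitude]]))
  lon <- suppressWarnings(as.numeric(tbl[[columns$longitude]]))
  if (any(stats::na.omit(lat) < -90 | stats::na.omit(lat) > 90) ||
      any(stats::na.omit(lon) < -180 | stats::na.omit(lon) > 180)) {
    stop("coordinates outside valid ranges", call. = FALSE)
  }
  flag <- rep("ok", nrow(tbl))
  flag[is.na(lat) | is.na(lon)] <- "no-coordinates"
  flag[!nzchar(seq)] <- "no-sequence"
  tibble::tibble(
    specimen_id = tbl[[columns$id]],
    source = "reference",
    latitude = lat,
    longitude = lon,
    COI = seq,
    flag = flag
  )
}

#' Summarise mitotype calls by collecting site
#'
#' Collapses per-worker African/European mitotype calls to per-site counts, the
#' unit at which foraging-site heterogeneity is assessed (the field protocol
#' samples three workers per floral resource). A site is `mixed` when both
#' mitotype classes occur among its workers, i.e. when workers from different
#' maternal lineages (hence different hives) attended the same resource.
#'
#' @param specimens Data frame with columns `specimen_id`, `site_id` and a
#'   mitotype call column with values `"african"`/`"european"`.
#' @param call_col Name of the call column (default `"mitotype"`).
#' @return Tibble with `site_id`, `n_bees`, `n_african_mito`, `mixed`, one row
#'   per site in order of first appearance.
#' @export
summarize_sites <- function(specimens, call_col = "mitotype") {
  need <- c("specimen_id", "site_id", call_col)
  miss <- setdiff(need, names(specimens))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  calls <- specimens[[call_col]]
  bad <- is.na(calls) | !calls %in% c("african", "european")
  if (any(bad)) {
    stop("specimen(s) without a mitotype call: ",
         paste(specimens$specimen_id[bad], collapse = ", "), call. = FALSE)
  }
  out <- dplyr::summarise(
    dplyr::group_by(specimens, site_id = .data$site_id),
    n_bees = dplyr::n(),
    n_african_mito = sum(.data[[call_col]] == "african"),
    .groups = "drop"
  )
  out$mixed <- out$n_african_mito > 0L & out$n_african_mito < out$n_bees
  out[match(unique(specimens$site_id), out$site_id), ]
}

#' Histogram of per-site African-mitotype counts
#'
#' Counts sites by how many of their `k` sampled workers carried the African
#' mitotype (0..k); this is the observed vector fed to
#' [heterogeneity_chisq()].
#'
#' @param site_summaries Output of [summarize_sites()] or [sample_sites()].
#' @param k Workers per site (defaults to the maximum `n_bees` present); sites
#'   with `n_bees != k` are excluded with a warning.
#' @return Named integer vector of length `k + 1` (names `"0"`..`"k"`).
#' @export
site_category_histogram <- function(site_summaries, k = NULL) {
  if (is.null(k)) k <- max(site_summaries$n_bees)
  keep <- site_summaries$n_bees == k
  if (!all(keep)) {
    warning(sprintf("excluding %d site(s) with n_bees != %d", sum(!keep), k),
            call. = FALSE)
  }
  x <- site_summaries$n_african_mito[keep]
  counts <- tabulate(x + 1L, nbins = k + 1L)
  stats::setNames(as.integer(counts), as.character(0:k))
}
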