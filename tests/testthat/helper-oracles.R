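# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Naive restriction digest: scan every substring position, split at cuts.
brute_digest <- function(seq, motif = "AGATCT", min_visible_bp = 0L,
                         cut_offset = 1L) {
  len <- nchar(seq)
  ml <- nchar(motif)
  cuts <- integer(0)
  for (i in seq_len(max(0L, len - ml + 1L))) {
    if (substr(seq, i, i + ml - 1L) == motif) {
      cuts <- c(cuts, i + cut_offset - 1L)
    }
  }
  cuts <- sort(unique(cuts[cuts >= 1L & cuts < len]))
  frags <- diff(c(0L, cuts, len))
  frags[frags >= min_visible_bp]
}

# Direct cell-by-cell chi-square summation.
oracle_gof <- function(k, n, p0) {
  obs <- c(k, n - k)
  exp <- c(n * p0, n * (1 - p0))
  sum((obs - exp)^2 / exp)
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

local_panel <- local({
  p <- NULL
  function() {
    if (is.null(p)) p <<- default_panel()
    p
  }
})
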