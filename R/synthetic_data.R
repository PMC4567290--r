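#' Simulation configuration for a two-component admixed population
#'
#' Describes the stated world of the generator: an admixed honey-bee
#' population in which a fraction `p_african` of workers carry the African
#' mitotype (default 0.65, the frequency reported among foraging workers in
#' the focal county), workers are sampled `bees_per_site` to a site (default
#' 3, the field protocol), and morphometrics are drawn from one of two
#' multivariate-normal components according to the bee's *nuclear* class.
#'
#' Nuclear class is linked to mitotype through a single parameter `lambda`:
#' with probability `lambda` a bee's nuclear class equals its mitotype, and
#' otherwise it is drawn independently as Bernoulli(`p_african`). `lambda = 1`
#' reproduces the early-introgression regime (mitotype predicts morphology);
#' `lambda = 0` reproduces the fully admixed regime with no
#' mitotype-morphology correlation.
#'
#' Measurement means and covariance are synthetic, honey-bee-plausible
#' placeholders, not empirical values: published sources print discriminant
#' score means rather than raw measurement moments. The covariance defaults to
#' a diagonal shape (SD 0.15, 0.12, 0.06, 0.08 mm for FWL, HWL, FL, TL)
#' rescaled once so the individual discriminant score has unit standard
#' deviation, and the two group means are calibrated (via
#' [calibrate_morph_means()]) so that their individual scores hit
#' `target_score_african` / `target_score_european`. The default targets are
#' symmetric at ±qnorm(1 − 0.099) ≈ ±1.2873, which makes the midpoint-0
#' classification rule misclassify 9.9% of individual workers — the expected
#' misclassification rate quoted for this discriminant.
#'
#' @param p_african African-mitotype frequency in (0, 1).
#' @param n_bees Number of workers for [sample_population()].
#' @param n_sites Number of sites for [sample_sites()].
#' @param bees_per_site Workers sampled per site.
#' @param lambda Mitotype-nuclear linkage in `[0, 1]` (see Details).
#' @param base_means Named 4-vector of baseline measurement means (mm).
#' @param morph_cov Optional 4x4 measurement covariance (mm^2); must be
#'   symmetric positive semi-definite. Default as described above.
#' @param target_score_african,target_score_european Individual-score
#'   calibration targets for the two nuclear classes.
#' @param misclass_individual Expected individual misclassification rate used
#'   to place the default targets; ignored when both targets are given.
#' @param seed Integer seed; fully determines all generator output.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(p_african = 0.65, n_bees = 300L, n_sites = 95L,
                       bees_per_site = 3L, lambda = 1,
                       base_means = c(FWL = 9.0, HWL = 6.3, FL = 2.6, TL = 3.2),
                       morph_cov = NULL,
                       target_score_african = NULL,
                       target_score_european = NULL,
                       misclass_individual = 0.099,
                       seed = 1L) {
  stopifnot(p_african > 0, p_african < 1, lambda >= 0, lambda <= 1,
            n_bees >= 1, n_sites >= 1, bees_per_site >= 1)
  meas <- c("FWL", "HWL", "FL", "TL")
  base_means <- base_means[meas]
  if (anyNA(base_means)) stop("base_means must name FWL, HWL, FL, TL", call. = FALSE)
  w <- discriminant_coefficients("individual")$weights[meas]
  if (is.null(morph_cov)) {
    shape <- diag(c(0.15, 0.12, 0.06, 0.08)^2)
    dimnames(shape) <- list(meas, meas)
    morph_cov <- shape / drop(t(w) %*% shape %*% w)  # unit score SD
  }
  morph_cov <- as.matrix(morph_cov)
  if (!isSymmetric(unname(morph_cov), tol = 1e-8)) {
    stop("morph_cov must be symmetric", call. = FALSE)
  }
  if (min(eigen(morph_cov, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("morph_cov must be positive semi-definite", call. = FALSE)
  }
  z <- stats::qnorm(1 - misclass_individual)
  if (is.null(target_score_african)) target_score_african <- -z
  if (is.null(target_score_european)) target_score_european <- z
  structure(list(
    p_african = p_african, n_bees = as.integer(n_bees),
    n_sites = as.integer(n_sites), bees_per_site = as.integer(bees_per_site),
    lambda = lambda, base_means = base_means, morph_cov = morph_cov,
    target_score_african = target_score_african,
    target_score_european = target_score_european,
    morph_means_african = calibrate_morph_means(base_means, target_score_african),
    morph_means_european = calibrate_morph_means(base_means, target_score_european),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  p_african = %.3f, lambda = %.2f, seed = %d\n",
              x$p_african, x$lambda, x$seed))
  cat(sprintf("  n_bees = %d; n_sites = %d x %d bees\n",
              x$n_bees, x$n_sites, x$bees_per_site))
  cat(sprintf("  score targets: african %.4f, european %.4f (score SD %.3f)\n",
              x$target_score_african, x$target_score_european,
              sqrt(drop(t(discriminant_coefficients("individual")$weights) %*%
                          x$morph_cov %*%
                          discriminant_coefficients("individual")$weights))))
  invisible(x)
}

#' Shift measurement means to hit a target discriminant score
#'
#' Moves a baseline measurement mean vector the minimal (Euclidean) distance
#' needed for its discriminant score to equal `target_score`: the shift is
#' along the coefficient vector, `base + ((target - score(base)) / (w.w)) w`.
#' Used to build generator group means from published score means when raw
#' measurement means are unavailable.
#'
#' @param base_means Named 4-vector (FWL, HWL, FL, TL) in mm.
#' @param target_score Desired score of the returned means.
#' @param formula Which discriminant the target refers to.
#' @return Named 4-vector whose score under the chosen formula equals
#'   `target_score` to machine precision.
#' @export
#' @examples
#' m <- calibrate_morph_means(c(FWL = 9, HWL = 6.3, FL = 2.6, TL = 3.2), -0.428)
#' individual_score(m[["FWL"]], m[["HWL"]], m[["FL"]], m[["TL"]])
calibrate_morph_means <- function(base_means, target_score,
                                  formula = c("individual", "colony_mean")) {
  formula <- match.arg(formula)
  meas <- c("FWL", "HWL", "FL", "TL")
  base_means <- base_means[meas]
  co <- discriminant_coefficients(formula)
  w <- co$weights[meas]
  if (sum(w^2) == 0) stop("zero coefficient vector", call. = FALSE)
  s0 <- sum(w * base_means) + co$constant
  base_means + ((target_score - s0) / sum(w^2)) * w
}

# Deterministic child seed so each generator component has its own stream.
.child_seed <- function(seed, id) {
  as.integer((as.double(seed) * 48271 + id) %% 2147483647)
}

#' Simulate an admixed worker population
#'
#' Draws `cfg$n_bees` workers: mitotype ~ Bernoulli(`p_african`), nuclear
#' class linked to mitotype with probability `lambda` (otherwise drawn
#' independently), morphometrics from the multivariate normal of the bee's
#' nuclear class, and (optionally) the three marker sequences constructed to
#' match the mitotype. Bees are grouped into sites of `bees_per_site` in
#' order. Output is fully reproducible from `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param sequences Attach marker sequences (slower; disable for large
#'   morphometry-only simulations).
#' @param panel Reference panel used to construct sequences.
#' @param n_extra_mutations Extra random substitutions per sequence, avoiding
#'   the restriction motif and the diagnostic site.
#' @return Tibble with `specimen_id`, `site_id`, `mitotype`, `nuclear_class`,
#'   the four measurement columns, and a `sequences` list-column when
#'   requested.
#' @export
sample_population <- function(cfg, sequences = TRUE, panel = default_panel(),
                              n_extra_mutations = 0L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.child_seed(cfg$seed, 1L))
  n <- cfg$n_bees
  mitotype <- ifelse(stats::runif(n) < cfg$p_african, "african", "european")
  linked <- stats::runif(n) < cfg$lambda
  indep <- ifelse(stats::runif(n) < cfg$p_african, "african", "european")
  nuclear <- ifelse(linked, mitotype, indep)
  morph <- matrix(NA_real_, n, 4,
                  dimnames = list(NULL, c("FWL", "HWL", "FL", "TL")))
  for (cls in c("african", "european")) {
    idx <- which(nuclear == cls)
    if (!length(idx)) next
    mu <- if (cls == "african") cfg$morph_means_african else cfg$morph_means_european
    morph[idx, ] <- MASS::mvrnorm(length(idx), mu = mu, Sigma = cfg$morph_cov)
  }
  out <- tibble::tibble(
    specimen_id = sprintf("bee%05d", seq_len(n)),
    site_id = sprintf("site%04d", ceiling(seq_len(n) / cfg$bees_per_site)),
    mitotype = mitotype,
    nuclear_class = nuclear,
    FWL = morph[, "FWL"], HWL = morph[, "HWL"],
    FL = morph[, "FL"], TL = morph[, "TL"]
  )
  if (sequences) {
    seed_pool <- sample.int(2147483646L, n)
    out$sequences <- lapply(seq_len(n), function(i) {
      make_marker_sequences(mitotype[i], panel = panel,
                            n_extra_mutations = n_extra_mutations,
                            seed = seed_pool[i])
    })
  }
  out
}

#' Simulate per-site African-mitotype counts
#'
#' Site counts drawn i.i.d. Binomial(`bees_per_site`, `p_african`) — the null
#' model of the site-heterogeneity test, in which the workers at a site are an
#' independent random draw from the whole foraging population.
#'
#' @param cfg A [sim_config()].
#' @return Tibble in [summarize_sites()] format (`site_id`, `n_bees`,
#'   `n_african_mito`, `mixed`).
#' @export
sample_sites <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.child_seed(cfg$seed, 2L))
  k <- cfg$bees_per_site
  counts <- stats::rbinom(cfg$n_sites, size = k, prob = cfg$p_african)
  tibble::tibble(
    site_id = sprintf("site%04d", seq_len(cfg$n_sites)),
    n_bees = k,
    n_african_mito = as.integer(counts),
    mixed = counts > 0L & counts < k
  )
}

.BASES <- c("A", "C", "G", "T")

.random_dna <- function(n) paste(sample(.BASES, n, replace = TRUE), collapse = "")

# Random sequence guaranteed free of the motif (rejection sampling).
.random_motif_free <- function(n, motif, max_tries = 10000L) {
  for (i in seq_len(max_tries)) {
    s <- .random_dna(n)
    if (!grepl(motif, s, fixed = TRUE)) return(s)
  }
  stop("failed to generate a motif-free sequence after ", max_tries,
       " attempts", call. = FALSE)
}

# Inject n substitutions avoiding `protect` positions; resample the whole set
# if the motif occurrence count changes (a mutation must not create or destroy
# a restriction site).
.mutate_seq <- function(seq, n, protect = integer(0), motif = NULL,
                        max_tries = 10000L) {
  if (n == 0L) return(seq)
  len <- nchar(seq)
  if (n > len - length(protect)) {
    stop("requested mutations exceed available positions", call. = FALSE)
  }
  count_motif <- function(s) {
    if (is.null(motif)) 0L else length(gregexpr(motif, s, fixed = TRUE)[[1]][
      gregexpr(motif, s, fixed = TRUE)[[1]] > 0])
  }
  target <- count_motif(seq)
  candidates <- setdiff(seq_len(len), protect)
  for (i in seq_len(max_tries)) {
    pos <- sample(candidates, n)
    v <- strsplit(seq, "")[[1]]
    for (p in pos) v[p] <- sample(setdiff(.BASES, v[p]), 1)
    s <- paste(v, collapse = "")
    if (count_motif(s) == target) return(s)
  }
  stop("failed to mutate without altering the restriction motif", call. = FALSE)
}

#' Construct marker sequences for a given mitotype
#'
#' Builds the three assay substrates so that, with no extra mutations, every
#' assay recovers the generating mitotype: a 485 bp cytochrome b amplicon that
#' is motif-free (African) or carries exactly one interior BglII site with
#' both fragments gel-visible (European); a COI barcode copied from the panel
#' reference with the diagnostic base set to C (African) or T (European); and
#' a spacer copied from the A exemplar (African) or a randomly chosen non-A
#' exemplar (European). Extra substitutions, if requested, avoid the motif and
#' the diagnostic coordinate and may not create new motif occurrences.
#'
#' @param mitotype `"african"` or `"european"`.
#' @param panel A [reference_panel()].
#' @param n_extra_mutations Substitutions injected into each sequence.
#' @param seed Optional integer seed for this call.
#' @return Named list with elements `cytb`, `COI`, `spacer`.
#' @export
make_marker_sequences <- function(mitotype = c("african", "european"),
                                  panel = default_panel(),
                                  n_extra_mutations = 0L, seed = NULL) {
  mitotype <- match.arg(mitotype)
  if (!is.null(seed)) set.seed(as.integer(seed))
  motif <- panel$restriction_motif
  amp_len <- 485L
  if (mitotype == "african") {
    cytb <- .random_motif_free(amp_len, motif)
  } else {
    # one interior site; both fragments comfortably above the visibility floor
    left_len <- 200L
    right_len <- amp_len - left_len - nchar(motif)
    repeat {
      cytb <- paste0(.random_motif_free(left_len, motif), motif,
                     .random_motif_free(right_len, motif))
      if (length(gregexpr(motif, cytb, fixed = TRUE)[[1]]) == 1L) break
    }
  }
  pos <- panel$coi_diagnostic_position
  coi <- panel$coi_reference
  substr(coi, pos, pos) <- if (mitotype == "african") "C" else "T"
  spacer <- if (mitotype == "african") {
    panel$spacer_exemplars[["A"]]
  } else {
    others <- setdiff(names(panel$spacer_exemplars), "A")
    panel$spacer_exemplars[[sample(others, 1)]]
  }
  if (n_extra_mutations > 0L) {
    motif_hits <- gregexpr(motif, cytb, fixed = TRUE)[[1]]
    protect_cytb <- if (motif_hits[1] > 0) {
      unlist(lapply(motif_hits, function(s) s:(s + nchar(motif) - 1L)))
    } else integer(0)
    cytb <- .mutate_seq(cytb, n_extra_mutations, protect_cytb, motif)
    coi <- .mutate_seq(coi, n_extra_mutations, protect = pos)
    spacer <- .mutate_seq(spacer, n_extra_mutations)
  }
  list(cytb = cytb, COI = coi, spacer = unname(spacer))
}

#' Write a simulated population to disk
#'
#' Emits the files the command-line `simulate` subcommand produces: a
#' measurements CSV, one FASTA per marker, and a truth TSV with the generating
#' mitotype and nuclear class of every bee.
#'
#' @param population Output of [sample_population()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_simulation <- function(population, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  meas <- population[, c("specimen_id", "site_id", "FWL", "HWL", "TL", "FL")]
  p <- file.path(dir, "measurements.csv")
  write_measurements(meas, p)
  paths <- c(paths, p)
  if ("sequences" %in% names(population)) {
    seqs <- unnest_sequences(population)
    for (mk in unique(seqs$marker)) {
      sub <- seqs[seqs$marker == mk, ]
      p <- file.path(dir, paste0(mk, ".fasta"))
      write_fasta(stats::setNames(sub$sequence, sub$specimen_id), p)
      paths <- c(paths, p)
    }
  }
  truth <- population[, c("specimen_id", "mitotype", "nuclear_class")]
  p <- file.path(dir, "truth.tsv")
  readr::write_tsv(truth, p)
  paths <- c(paths, p)
  invisible(paths)
}
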