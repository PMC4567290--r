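test_that("calibrate_morph_means hits the target score exactly", {
  base <- c(FWL = 9.0, HWL = 6.0, FL = 2.6, TL = 3.2)
  # zero shift when the base already scores the target
  s0 <- individual_score(base[["FWL"]], base[["HWL"]], base[["FL"]], base[["TL"]])
  expect_equal(calibrate_morph_means(base, s0), base)
  # published-mean target plugs back in exactly
  m <- calibrate_morph_means(base, -0.428)
  expect_equal(
    individual_score(m[["FWL"]], m[["HWL"]], m[["FL"]], m[["TL"]], check = FALSE),
    -0.428, tolerance = 1e-9
  )
  # constant-term identity: all-zero base, target = the constant
  z <- calibrate_morph_means(c(FWL = 0, HWL = 0, FL = 0, TL = 0), -36.4909)
  expect_equal(unname(z), c(0, 0, 0, 0), tolerance = 1e-12)
  # colony formula calibration works the same way
  mc <- calibrate_morph_means(base, -1.0, formula = "colony_mean")
  expect_equal(suppressWarnings(
    colony_score(mc[["FWL"]], mc[["HWL"]], mc[["FL"]], mc[["TL"]])
  ), -1.0, tolerance = 1e-9)
})

test_that("sim_config validates its stated world and is deterministic", {
  cfg <- sim_config(seed = 5)
  # covariance is scaled so the individual score has unit SD
  w <- discriminant_coefficients("individual")$weights
  expect_equal(drop(t(w) %*% cfg$morph_cov %*% w), 1, tolerance = 1e-12)
  # default targets straddle zero at the 9.9% misclassification quantile
  expect_equal(cfg$target_score_african, -qnorm(1 - 0.099))
  expect_equal(cfg$target_score_european, qnorm(1 - 0.099))
  expect_error(sim_config(p_african = 0), "p_african")
  expect_error(sim_config(morph_cov = matrix(c(1, 2, 3, 4, 1, 1, 1, 1, 1,
                                               1, 1, 1, 1, 1, 1, 1), 4, 4)),
               "symmetric")
  bad <- diag(4); bad[1, 1] <- -1
  expect_error(sim_config(morph_cov = bad), "semi-definite")
  # identical config => byte-identical output
  a <- sample_population(sim_config(n_bees = 40, seed = 9))
  b <- sample_population(sim_config(n_bees = 40, seed = 9))
  expect_identical(a, b)
  s1 <- sample_sites(sim_config(n_sites = 50, seed = 9))
  s2 <- sample_sites(sim_config(n_sites = 50, seed = 9))
  expect_identical(s1, s2)
})

test_that("sample_population draws mitotypes at p_african and respects lambda", {
  # p_african = 1 (approached): all bees African
  cfg <- sim_config(p_african = 1 - 1e-12, n_bees = 100, seed = 2)
  expect_true(all(sample_population(cfg, sequences = FALSE)$mitotype == "african"))
  # frequency recovery within the binomial 99% interval at n = 5000
  pop <- sample_population(sim_config(n_bees = 5000, seed = 3), sequences = FALSE)
  p_hat <- mean(pop$mitotype == "african")
  expect_true(p_hat > 0.63 && p_hat < 0.67)
  # lambda = 1: nuclear class equals mitotype
  expect_equal(pop$nuclear_class, pop$mitotype)
  # lambda = 0: no mitotype-morphology association (null t)
  pop0 <- sample_population(sim_config(n_bees = 5000, lambda = 0, seed = 4),
                            sequences = FALSE)
  sc <- individual_score(pop0$FWL, pop0$HWL, pop0$FL, pop0$TL)
  tt <- pooled_t(sc[pop0$mitotype == "african"], sc[pop0$mitotype == "european"])
  expect_lt(abs(tt$t), 3)
})

test_that("simulated score means converge to the calibration targets", {
  cfg <- sim_config(n_bees = 5000, lambda = 0,
                    target_score_african = -1.473,
                    target_score_european = -1.180, seed = 8)
  pop <- sample_population(cfg, sequences = FALSE)
  sc <- individual_score(pop$FWL, pop$HWL, pop$FL, pop$TL, check = FALSE)
  for (cls in c("african", "european")) {
    target <- if (cls == "african") -1.473 else -1.180
    x <- sc[pop$nuclear_class == cls]
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - target), 3 * se)
  }
})

test_that("sample_sites follows the binomial site model", {
  cfg <- sim_config(p_african = 1e-12, n_sites = 50, seed = 1)
  sites <- sample_sites(cfg)
  expect_true(all(sites$n_african_mito == 0))
  expect_true(all(!sites$mixed))
  # mixed-site fraction ~ P(1) + P(2) = 3 p q at k = 3
  big <- sample_sites(sim_config(n_sites = 20000, seed = 12))
  expect_lt(abs(mean(big$mixed) - 3 * 0.65 * 0.35), 0.01)
})

test_that("make_marker_sequences constructs assay-consistent sequences", {
  panel <- local_panel()
  afr <- make_marker_sequences("african", panel, seed = 21)
  eur <- make_marker_sequences("european", panel, seed = 22)
  expect_equal(rflp_mitotype(afr$cytb, panel)$call, "african")
  expect_equal(coi_snp_call(afr$COI, panel)$call, "african")
  expect_equal(spacer_lineage(afr$spacer, panel)$call, "lineage_A")
  expect_equal(rflp_mitotype(eur$cytb, panel)$call, "european")
  expect_equal(coi_snp_call(eur$COI, panel)$call, "european")
  expect_true(spacer_lineage(eur$spacer, panel)$call %in%
                c("lineage_C", "lineage_M", "lineage_O"))
  expect_error(make_marker_sequences("african", panel, n_extra_mutations = 1e6,
                                     seed = 1), "exceed")
})

test_that("marker round trip survives a few extra mutations", {
  panel <- local_panel()
  for (i in 1:20) {
    mito <- if (i %% 2) "african" else "european"
    sq <- make_marker_sequences(mito, panel, n_extra_mutations = 5, seed = 300 + i)
    expect_equal(rflp_mitotype(sq$cytb, panel)$call, mito)
    expect_equal(coi_snp_call(sq$COI, panel)$call, mito)
    lg <- spacer_lineage(sq$spacer, panel)$call
    if (mito == "african") {
      expect_equal(lg, "lineage_A")
    } else {
      expect_true(lg %in% c("lineage_C", "lineage_M", "lineage_O"))
    }
  }
})

test_that("write_simulation emits measurements, FASTA per marker, and truth", {
  dir <- withr::local_tempdir()
  pop <- sample_population(sim_config(n_bees = 6, seed = 44))
  paths <- write_simulation(pop, dir)
  expect_true(file.exists(file.path(dir, "measurements.csv")))
  meas <- read_measurements(file.path(dir, "measurements.csv"))
  expect_equal(meas$specimen_id, pop$specimen_id)
  expect_equal(meas$FWL, pop$FWL)
  fa <- read_fasta(file.path(dir, "cytb.fasta"))
  expect_equal(fa$id, pop$specimen_id)
  truth <- readr::read_tsv(file.path(dir, "truth.tsv"),
                           show_col_types = FALSE)
  expect_equal(truth$mitotype, pop$mitotype)
})
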