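# TPP scoring: fold changes, abundance/stability scores, z-transform,
# significance and classification

make_matrix <- function(treat, ctrl, temps = TPP_TEMPERATURES) {
  arr <- array(NA_real_, dim = c(nrow(ctrl), length(temps), 2L),
               dimnames = list(rownames(ctrl), as.character(temps),
                               c("DMSO", "drug")))
  arr[, , "DMSO"] <- ctrl
  arr[, , "drug"] <- treat
  melt_curve_matrix(arr, temperatures = temps, control = "DMSO")
}

test_that("fold changes are log2 ratios with zero/missing censoring", {
  ctrl <- matrix(100, 3, 10, dimnames = list(c("a", "b", "c"), NULL))
  treat <- ctrl
  treat["b", ] <- 200          # doubling
  treat["c", 3] <- 0           # zero intensity -> missing
  treat["c", 4] <- NA
  m <- make_matrix(treat, ctrl)
  fc <- suppressWarnings(compute_fold_changes(m, "drug"))
  expect_equal(unname(fc$log2fc["a", ]), rep(0, 10))
  expect_equal(unname(fc$log2fc["b", ]), rep(1, 10))
  expect_true(all(is.na(fc$log2fc["c", 3:4])))
  expect_equal(unname(fc$n_points), c(10, 10, 8))
  expect_warning(compute_fold_changes(m, "drug"), "zero intensities")
  expect_error(compute_fold_changes(m, "nope"), "unknown treatment")
  expect_error(compute_fold_changes(m, "DMSO", "DMSO"), "must differ")
})

test_that("abundance score averages the two lowest temperatures", {
  row <- rbind(c(0.4, 0.6, rep(0, 8)))
  expect_equal(unname(abundance_score(row)), 0.5)
  expect_equal(unname(abundance_score(rbind(rep(0, 10)))), 0)
  missing_low <- rbind(c(NA, 0.6, rep(0, 8)))
  expect_true(is.na(abundance_score(missing_low)))
})

test_that("stability score sums abundance-corrected fold changes", {
  const <- rbind(rep(0.7, 10))
  expect_equal(unname(stability_score(const, abundance_score(const))), 0)
  row <- rbind(c(0, 0, rep(1, 8)))
  expect_equal(unname(stability_score(row, abundance_score(row))), 8)
})

test_that("stability score is shift-invariant and antisymmetric", {
  set.seed(42)
  for (i in 1:20) {
    row <- rbind(rnorm(10))
    s0 <- stability_score(row, abundance_score(row))
    shifted <- row + rnorm(1)
    expect_equal(stability_score(shifted, abundance_score(shifted)), s0)
    expect_equal(stability_score(-row, abundance_score(-row)), -s0)
    # abundance shifts by exactly the added constant
    k <- 0.37
    expect_equal(abundance_score(row + k), abundance_score(row) + k)
  }
})

test_that("min_points governs when a stability score is defined", {
  row <- rbind(c(rep(0.5, 9), NA))
  ab <- abundance_score(row)
  expect_true(is.na(stability_score(row, ab, min_points = 10)))
  expect_false(is.na(stability_score(row, ab, min_points = 9)))
})

test_that("z transform matches the (n-1)-sd convention and idempotence", {
  expect_equal(z_transform(c(1, 2, 3)), c(-1, 0, 1))
  z <- z_transform(rnorm(100, 5, 3))
  expect_equal(z_transform(z), z, tolerance = 1e-12)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_error(z_transform(rep(1, 5)), "zero standard deviation")
  expect_error(z_transform(c(1, NA, NA)), "at least two")
  expect_true(is.na(z_transform(c(1, 2, NA))[3]))
})

test_that("empirical-null significance is calibrated on pure noise", {
  # Monte-Carlo calibration: on iid standard-normal scores the rejection
  # rate at p < 0.05 must be 5%. A single n = 5000 draw carries ~0.5%
  # noise from the binomial count plus the MAD scale estimate, so the
  # check averages replicates and bounds each one loosely.
  fractions <- vapply(1:10, function(s) {
    set.seed(s)
    mean(moderated_significance(rnorm(5000), weights = 10)$p_value < 0.05)
  }, numeric(1))
  expect_lt(abs(mean(fractions) - 0.05), 0.005)
  expect_true(all(abs(fractions - 0.05) < 0.02))
  # z at the null center gets p = 1
  sym <- c(-(1:50) / 25, 0, (1:50) / 25)
  p0 <- moderated_significance(sym, weights = 1)$p_value[51]
  expect_equal(p0, 1, tolerance = 1e-9)
})

test_that("spiked outliers get small FDR, and FDR is monotone in p", {
  set.seed(8)
  z <- c(rnorm(950), rnorm(50, mean = 6, sd = 0.1))
  sig <- moderated_significance(z, weights = 10)
  expect_true(all(sig$fdr[951:1000] < 0.05))
  ord <- order(sig$p_value)
  expect_true(all(diff(sig$fdr[ord]) >= -1e-12))
  # local-fdr variant also flags the spike
  sig_l <- moderated_significance(z, weights = 10, fdr_method = "local")
  expect_true(all(sig_l$fdr[951:1000] < 0.05))
})

test_that("weights rescale the per-protein null variance", {
  set.seed(9)
  z <- rnorm(1000)
  full <- moderated_significance(z, weights = 10)$p_value
  half <- moderated_significance(z, weights = c(rep(5, 500), rep(10, 500)))
  # down-weighted observations have wider nulls, hence larger p
  expect_true(median(half$p_value[1:500] - full[1:500]) > 0)
  expect_error(moderated_significance(rnorm(5)), "fewer than 10")
  expect_error(moderated_significance(z, weights = 0.5), ">= 1")
})

test_that("classification follows the two-arm cutoff rule", {
  # published examples: DLD-like (significant FDR, small z) stays
  # unaffected; HDAC1-like (z = 3.58, tiny FDR) is stabilized
  z <- c(0.66, 3.58, -2.0, -3.0, NA)
  fdr <- c(2.6e-4, 1.8e-14, 0.5, 1e-3, 0.01)
  cls <- classify_stability(z, fdr)
  expect_equal(as.character(cls),
               c("unaffected", "stabilized", "unaffected",
                 "destabilized", "unaffected"))
})

test_that("the pipeline recovers planted melting shifts", {
  sim <- gen_tpp(n_proteins = 300, n_stabilized = 15, delta_tm = 2,
                 noise_cv = 0.05, seed = 21)
  fit <- tpp_stability(sim$curves, "treated")
  stab_ids <- sim$truth$protein_id[sim$truth$class == "stabilized"]
  aff <- fit$table$protein_id %in% stab_ids
  expect_true(mean(fit$table$stability_score[aff] > 0) >= 0.95)
  expect_gt(median(fit$table$stability_score[aff]),
            median(fit$table$stability_score[!aff]))
  # no planted effect -> almost nothing classified
  null_sim <- gen_tpp(n_proteins = 300, noise_cv = 0.05, seed = 22)
  null_fit <- tpp_stability(null_sim$curves, "treated")
  expect_lte(mean(null_fit$table$class != "unaffected"), 0.05)
})

test_that("noiseless fold changes match the generator's curve ratio", {
  sim <- gen_tpp(n_proteins = 50, n_stabilized = 10, delta_tm = 2,
                 noise_cv = 0, seed = 31)
  fc <- compute_fold_changes(sim$curves, "treated")
  temps <- sim$curves$temperatures
  for (i in seq_len(50)) {
    tr <- sim$truth[i, ]
    expected <- log2(melt_fraction(temps, tr$tm + tr$delta_tm) /
                       melt_fraction(temps, tr$tm))
    expect_equal(unname(fc$log2fc[tr$protein_id, ]), expected,
                 tolerance = 1e-12)
    # analytic stability score agrees with the pipeline
    ab <- abundance_score(fc$log2fc[tr$protein_id, , drop = FALSE])
    st <- stability_score(fc$log2fc[tr$protein_id, , drop = FALSE], ab)
    expect_equal(unname(st),
                 analytic_stability(tr$tm, tr$delta_tm, temps),
                 tolerance = 1e-9)
  }
  # pure abundance effect: score equals the planted log2 shift
  sim_a <- gen_tpp(n_proteins = 20, n_abundance_shifted = 5,
                   delta_abundance = 0.8, noise_cv = 0, seed = 32)
  fc_a <- compute_fold_changes(sim_a$curves, "treated")
  shifted <- sim_a$truth$class == "abundance_shifted"
  ab_a <- abundance_score(fc_a$log2fc)
  expect_equal(unname(ab_a[shifted]), rep(0.8, 5), tolerance = 1e-12)
  expect_equal(unname(stability_score(fc_a$log2fc, ab_a)[shifted]),
               rep(0, 5), tolerance = 1e-9)
})

test_that("contrasts against one control are computed independently", {
  temps <- TPP_TEMPERATURES
  arr <- array(100, dim = c(25, 10, 3),
               dimnames = list(sprintf("p%02d", 1:25),
                               as.character(temps),
                               c("DMSO", "drugA", "drugA_stress")))
  set.seed(99)
  arr[, , "drugA"] <- arr[, , "drugA"] * 2^matrix(rnorm(250, sd = 0.1), 25)
  arr[, , "drugA_stress"] <- 100 * 2^matrix(rnorm(250, 1, 0.1), 25)
  m <- melt_curve_matrix(arr, temperatures = temps, control = "DMSO")
  fa <- tpp_stability(m, "drugA")
  fb <- tpp_stability(m, "drugA_stress")
  # the second contrast's uniform doubling shows up only in its own
  # abundance scores; the first contrast is untouched by it
  expect_equal(mean(fb$table$abundance_score), 1, tolerance = 0.1)
  expect_equal(mean(fa$table$abundance_score), 0, tolerance = 0.1)
  fa2 <- tpp_stability(m[["intensity"]][, , c(1, 2)] |>
                         (\(x) melt_curve_matrix(x, temps))(), "drugA")
  expect_equal(fa2$table$stability_z, fa$table$stability_z)
})

test_that("stability table round-trips through TSV and prints", {
  sim <- gen_tpp(n_proteins = 30, n_stabilized = 3, seed = 41)
  fit <- tpp_stability(sim$curves, "treated")
  expect_s3_class(fit, "tpp_stability")
  expect_output(print(fit), "TPP stability analysis")
  expect_output(print(summary(fit)), "Top hits")
  path <- tempfile(fileext = ".tsv")
  write_stability_table(fit, path)
  back <- read.delim(path)
  expect_equal(nrow(back), 30)
  expect_equal(back$stability_z, fit$table$stability_z, tolerance = 1e-12)
})
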