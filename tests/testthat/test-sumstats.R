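# Reading summary statistics and converting between Z, effect/SE, OR and
# p-value scales.

test_that("Z and p are derived from beta/SE tables", {
  path <- write_sumstats_fixture(data.frame(
    SNP = c("rs1", "rs2", "rs3"), CHR = 1, BP = c(100, 200, 300),
    BETA = 0.2, SE = 0.1))
  st <- read_sumstats(path)
  expect_equal(st$z, rep(2, 3))
  expect_equal(st$p, rep(2 * pnorm(-2), 3), tolerance = 1e-12)
  expect_equal(st$effect, rep(0.2, 3))
})

test_that("OR/SE and p+direction combinations give the expected Z", {
  path <- write_sumstats_fixture(data.frame(
    SNP = "rs1", CHR = 2, BP = 50, OR = 1.0, SE = 0.1))
  expect_equal(read_sumstats(path)$z, 0)

  path2 <- write_sumstats_fixture(data.frame(
    SNP = "rs9", CHR = 3, BP = 10, P = 0.0455, DIRECTION = "-"))
  expect_equal(read_sumstats(path2)$z, -2.0, tolerance = 5e-3)
})

test_that("delimiters are auto-detected", {
  df <- data.frame(SNP = c("a", "b"), CHR = 1, BP = c(1, 2), Z = c(1.5, -0.5))
  for (sep in c("\t", ",", " ")) {
    st <- read_sumstats(write_sumstats_fixture(df, sep = sep))
    expect_equal(st$z, c(1.5, -0.5))
  }
})

test_that("rows out of domain are dropped and counted; bad files error", {
  path <- write_sumstats_fixture(data.frame(
    SNP = c("a", "b", "c", "d"), CHR = 1, BP = c(1, 2, 3, 4),
    BETA = c(0.1, 0.2, 0.3, 0.4), SE = c(0.1, -1, 0.1, 0.1),
    P = c(0.32, 0.5, 2, 0.0001)))
  expect_warning(st <- read_sumstats(path), "inconsistent")
  expect_equal(st$variant_id, c("a", "d"))
  expect_equal(attr(st, "load_report")$n_dropped, 2)

  # missing required logical column
  path2 <- write_sumstats_fixture(data.frame(SNP = "a", BP = 1, Z = 1))
  expect_error(read_sumstats(path2), class = "wincurse_config_error")
  # no statistic combination
  path3 <- write_sumstats_fixture(data.frame(SNP = "a", CHR = 1, BP = 1, P = 0.5))
  expect_error(read_sumstats(path3), class = "wincurse_config_error")
  # column_map naming an absent column
  path4 <- write_sumstats_fixture(data.frame(SNP = "a", CHR = 1, BP = 1, Z = 1))
  expect_error(read_sumstats(path4, column_map = c(z = "ZSCORE_X")),
               class = "wincurse_config_error")
})

test_that("tables are sorted by (chrom, pos) and duplicate IDs rejected", {
  st <- scan_stats(c("a", "b", "c", "d"), chrom = c("2", "1", "1", "10"),
                   pos_bp = c(5, 500, 10, 1), z = c(1, 2, 3, 4))
  expect_equal(st$variant_id, c("c", "b", "a", "d"))
  expect_error(scan_stats(c("a", "a"), c(1, 1), c(1, 2), z = c(1, 2)),
               class = "wincurse_input_error")
})

test_that("z_from_effect_se is the plain ratio and rejects bad SE", {
  expect_equal(z_from_effect_se(0.2, 0.1), 2.0)
  expect_equal(z_from_effect_se(0, 0.5), 0)
  expect_equal(z_from_effect_se(log(1.25), 0.05), 4.4629, tolerance = 1e-4)
  expect_error(z_from_effect_se(1, 0), class = "wincurse_domain_error")
})

test_that("z_from_pvalue_sign inverts the two-sided p convention", {
  expect_equal(z_from_pvalue_sign(1, +1), 0)
  expect_equal(z_from_pvalue_sign(0.0455, -1), -2.0, tolerance = 5e-3)
  expect_equal(z_from_pvalue_sign(5e-8, +1), 5.4513, tolerance = 1e-4)
  expect_error(z_from_pvalue_sign(0, 1), class = "wincurse_domain_error")
  expect_error(z_from_pvalue_sign(1.5, 1), class = "wincurse_domain_error")
})

test_that("p -> z round-trips to 1e-6 relative up to |z| = 37 and handles extremes", {
  z <- c(seq(0.1, 37, length.out = 40), -seq(1, 36, by = 5))
  back <- z_from_pvalue_sign(pvalue_from_z(z), sign(z))
  expect_equal(back, z, tolerance = 1e-6)
  # smallest representable p still maps to a finite Z
  expect_true(is.finite(z_from_pvalue_sign(1e-308, 1)))
  # strictly decreasing in p
  p <- sort(runif(50, 1e-12, 1))
  expect_true(all(diff(z_from_pvalue_sign(p, 1)) < 0))
})

test_that("adjusted effects back-transform on both scales", {
  expect_equal(adjusted_effect_from_z(2.0, se = 0.1), 0.2)
  expect_equal(adjusted_effect_from_z(0, se = 0.25), 0)
  expect_equal(adjusted_effect_from_z(1.5, mode = "ratio_scale",
                                      z_raw = 3.0, effect_raw = 0.6), 0.3)
  expect_error(adjusted_effect_from_z(1, mode = "ratio_scale",
                                      z_raw = 0, effect_raw = 1),
               class = "wincurse_domain_error")
  # linear in z_adj on the se scale; scales agree when effect = se * z
  z_adj <- c(-2, 0, 1, 3)
  expect_equal(adjusted_effect_from_z(2 * z_adj, se = 0.3),
               2 * adjusted_effect_from_z(z_adj, se = 0.3))
  expect_equal(adjusted_effect_from_z(1.2, se = 0.3),
               adjusted_effect_from_z(1.2, mode = "ratio_scale",
                                      z_raw = 2, effect_raw = 0.3 * 2))
})

test_that("write_adjusted round-trips and aligns estimate columns", {
  st <- scan_stats(paste0("rs", 1:10), chrom = 1, pos_bp = 1:10 * 100,
                   z = rnorm(10))
  e1 <- fiqt(st$z)
  e2 <- mle_estimate(st$z)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_adjusted(st, list(e1, e2), path)
  back <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(ncol(back), ncol(as.data.frame(st)) + 2)
  expect_equal(back$z, st$z, tolerance = 1e-6)
  expect_equal(back$FIQT, e1$values, tolerance = 1e-6)

  # empty estimate list copies the table verbatim
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_adjusted(st, list(), path2)
  expect_equal(ncol(read.table(path2, header = TRUE, sep = "\t")),
               ncol(as.data.frame(st)))
  # misaligned estimates refuse to write
  expect_error(write_adjusted(st, mle_estimate(1:3), path),
               class = "wincurse_input_error")
})
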