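# summary statistics I/O, harmonization and reconstruction of z and V

test_that("read_summary harmonizes OR/SE input and log-transforms the OR", {
  path <- write_daner_file(data.frame(
    SNP = c("rs1", "rs2", "rs3"), CHR = 1, BP = 1:3,
    OR = c(1.0, 1.2, 0.9), SE = c(0.1, 0.05, 0.2), P = c(0.9, 0.0002, 0.6)))
  tab <- read_summary(path)
  expect_s3_class(tab, "spebf_summary")
  expect_equal(tab$beta_hat, log(c(1.0, 1.2, 0.9)))
  expect_equal(tab$var, c(0.01, 0.0025, 0.04))
  expect_equal(tab$beta_hat[1], 0)
})

test_that("MAF QC drops low-frequency rows and accounts for every raw row", {
  path <- write_daner_file(data.frame(
    SNP = sprintf("rs%d", 1:5), CHR = 1, BP = 1:5,
    OR = c(1.1, 1.2, 0.95, 1.05, 1.3), SE = 0.1,
    P = 0.5, FRQ_U = c(0.3, 0.005, 0.2, 0.009, 0.4)))
  expect_warning(tab <- read_summary(path, qc = qc_options(maf_min = 0.01)),
                 "low_maf")
  prov <- attr(tab, "provenance")
  expect_equal(prov$drops$low_maf, 2L)
  expect_equal(prov$n_retained + sum(unlist(prov$drops)), prov$n_raw)
  expect_equal(nrow(tab), 3L)
  # MAF absent entirely: rows retained
  path2 <- write_daner_file(data.frame(SNP = "rs1", CHR = 1, BP = 1,
                                       OR = 1.1, SE = 0.1, P = 0.5))
  expect_equal(nrow(read_summary(path2)), 1L)
})

test_that("variance is reconstructed from (beta, p) and round-trips losslessly", {
  set.seed(11)
  m <- 20
  beta <- rnorm(m, 0, 0.2)
  p <- runif(m, 1e-12, 0.99)
  path <- write_daner_file(data.frame(SNP = sprintf("rs%d", 1:m), CHR = 2,
                                      BP = 1:m, BETA = beta, P = p))
  cmap <- list(snp_id = "SNP", chrom = "CHR", pos = "BP", beta = "BETA", p = "P")
  tab <- read_summary(path, column_map = cmap)
  expect_equal(tab$var, derive_var_from_p(beta, p), tolerance = 1e-12)
  # read -> write -> read identity on (snp_id, beta_hat, var) to 12 sig digits
  path2 <- tempfile(fileext = ".tsv")
  write_summary(tab, path2)
  tab2 <- read_summary(path2, column_map = summary_column_map())
  expect_identical(tab2$snp_id, tab$snp_id)
  expect_equal(tab2$beta_hat, tab$beta_hat, tolerance = 1e-12)
  expect_equal(tab2$var, tab$var, tolerance = 1e-12)
})

test_that("harmonization is idempotent and z is consistent after read", {
  path <- write_daner_file(data.frame(
    SNP = sprintf("rs%d", 1:8), CHR = 1, BP = 1:8,
    OR = exp(seq(-0.3, 0.3, length.out = 8)), SE = seq(0.05, 0.2, length.out = 8),
    P = 0.5))
  tab <- read_summary(path)
  expect_true(all(abs(tab$z - tab$beta_hat / sqrt(tab$var)) /
                    pmax(abs(tab$z), 1) <= 0.01))
  path2 <- tempfile(); write_summary(tab, path2)
  tab2 <- read_summary(path2, column_map = summary_column_map())
  path3 <- tempfile(); write_summary(tab2, path3)
  expect_identical(readLines(path2), readLines(path3))
})

test_that("column-map and degenerate-input errors are informative", {
  path <- write_daner_file(data.frame(SNP = "rs1", CHR = 1, BP = 1,
                                      OR = 1.1, SE = 0.1, P = 0.5))
  expect_error(read_summary(path, column_map = list(beta = "BETA", p = "P")),
               "snp_id")
  expect_error(read_summary(path, column_map = list(snp_id = "SNP", p = "P")),
               "beta")
  expect_error(read_summary(path, column_map = list(snp_id = "SNP", or = "OR")),
               "se")
})

test_that("duplicate snp_id keeps first occurrence; se wins over conflicting var", {
  path <- write_daner_file(data.frame(
    SNP = c("rs1", "rs1", "rs2"), CHR = 1, BP = 1:3,
    OR = c(1.1, 1.4, 1.2), SE = c(0.1, 0.1, 0.2),
    VAR = c(0.01, 0.01, 0.08), P = 0.5))
  cmap <- list(snp_id = "SNP", chrom = "CHR", pos = "BP", or = "OR",
               se = "SE", var = "VAR")
  warns <- capture_warnings(tab <- read_summary(path, column_map = cmap))
  expect_match(warns, "duplicate", all = FALSE)
  expect_match(warns, "se wins", all = FALSE)
  expect_equal(tab$beta_hat[tab$snp_id == "rs1"], log(1.1))
  expect_equal(tab$var[tab$snp_id == "rs2"], 0.04)  # se^2, not VAR = 0.08
})

test_that("z_from_p is exact at the center and tail-stable in the extremes", {
  expect_lt(abs(z_from_p(0.9999999, 1)), 1e-6)
  expect_equal(z_from_p(0.05, 1), 1.959964, tolerance = 1e-6)
  # frozen from two-sided bisection of 2*pnorm(-z) = 6.97e-10
  expect_equal(z_from_p(6.97e-10, 1), 6.17, tolerance = 0.005)
  expect_equal(z_from_p(6.97e-10, -1), -6.166768, tolerance = 1e-6)
  # extreme tail: finite, monotone, and inverts pnorm to high precision
  z <- z_from_p(1e-300, 1)
  expect_true(is.finite(z) && z > 37)
  expect_equal(2 * pnorm(-z), 1e-300, tolerance = 1e-12)
  expect_error(z_from_p(0, 1), "p must lie")
  expect_error(z_from_p(1, 1), "p must lie")
})

test_that("derive_var_from_p inverts the Wald relation", {
  # Table-1-style published inputs
  expect_equal(derive_var_from_p(0.271, 6.97e-10), 1.93e-3, tolerance = 0.005)
  # z = 1 case: V ~ beta^2
  expect_equal(derive_var_from_p(0.4, 0.3173), 0.16, tolerance = 1e-3)
  # algebraic inverse property over random inputs
  set.seed(3)
  b <- runif(200, -1, 1); b <- b[b != 0]
  p <- 10^runif(length(b), -30, -0.1)
  v <- derive_var_from_p(b, p)
  expect_equal(abs(z_from_p(p, sign(b))) * sqrt(v), abs(b), tolerance = 1e-10)
  expect_error(derive_var_from_p(0, 0.5), "undefined|supply")
})

test_that("write_results enforces its schema and round-trips ranks exactly", {
  tab <- make_toy_summary(m = 25, seed = 2)
  np <- make_random_prior(B = 20, span = 0.4)
  bft <- rank_table(tab, abf_prior(), np)
  path <- tempfile(fileext = ".tsv")
  write_results(bft, path)
  lines <- readLines(path)
  expect_equal(lines[1], paste(
    c("snp_id", "chrom", "pos", "beta_hat", "var", "z", "p", "abf",
      "log10_abf", "spebf", "log10_spebf", "post_null_prob",
      "rank_p", "rank_abf", "rank_spebf"), collapse = "\t"))
  expect_length(lines, 26L)
  back <- read_results(path)
  expect_identical(back$rank_p, bft$rank_p)
  expect_identical(back$rank_abf, bft$rank_abf)
  expect_identical(back$rank_spebf, bft$rank_spebf)
  # 1-row table -> header + one row; empty table errors without writing
  one <- rank_table(tab[1, ], abf_prior(), np)
  p1 <- tempfile(); write_results(one, p1)
  expect_length(readLines(p1), 2L)
  p2 <- tempfile()
  expect_error(write_results(bft[0, ], p2), "empty")
  expect_false(file.exists(p2))
})
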