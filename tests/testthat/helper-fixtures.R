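# shared fixtures: tiny summary tables and files built in code

# write a daner-style (SNP/CHR/BP/OR/SE/P[/FRQ_U]) toy file, return its path
write_daner_file <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# small deterministic summary table built directly (no file round trip)
make_toy_summary <- function(m = 50, seed = 7, v = NULL) {
  set.seed(seed)
  beta <- rnorm(m, 0, 0.1)
  if (is.null(v)) v <- runif(m, 5e-4, 5e-3)
  if (length(v) == 1L) v <- rep(v, m)
  summary_table(data.frame(
    snp_id = sprintf("rs%05d", seq_len(m)), chrom = "1", pos = seq_len(m),
    beta_hat = beta, var = v, stringsAsFactors = FALSE))
}

# random valid nonparametric prior on a symmetric grid
make_random_prior <- function(B = 20, seed = 1, span = 0.5, pi = 0.1) {
  set.seed(seed)
  t <- make_grid(span, B = B, span_factor = 1)
  p <- rexp(B)
  nonparam_prior(t, p / sum(p), pi)
}
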