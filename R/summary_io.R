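#' QC options for reading summary statistics
#'
#' @param maf_min Minimum minor allele frequency retained.  Rows with a
#'   reported MAF below this are dropped; rows with no MAF column are kept
#'   (MAF is optional).  The conventional GWAS cutoff is 1\%.
#' @return A list of class `spebf_qc`.
#' @export
qc_options <- function(maf_min = 0.01) {
  stopifnot(is.numeric(maf_min), length(maf_min) == 1L, maf_min >= 0, maf_min < 0.5)
  structure(list(maf_min = maf_min), class = "spebf_qc")
}

#' Construct a validated summary-statistics table
#'
#' Lightweight container used throughout the package: a data.frame with
#' columns `snp_id`, `chrom`, `pos`, `beta_hat`, `var`, `z`, `p` and
#' optionally `maf`, carrying provenance as an attribute.  Chromosome and
#' position are opaque pass-through labels; the methods never use position
#' arithmetically.
#'
#' @param df data.frame with at least `snp_id`, `beta_hat`, `var`; `z` and
#'   `p` are filled in from `beta_hat`/`var` when absent.
#' @param provenance list recording the source and any QC counts.
#' @return A data.frame of class `spebf_summary`.
#' @export
summary_table <- function(df, provenance = list()) {
  stopifnot(is.data.frame(df))
  req <- c("snp_id", "beta_hat", "var")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("summary_table: missing required column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop("summary_table: empty table")
  if (!("chrom" %in% names(df))) df$chrom <- "NA"
  if (!("pos" %in% names(df))) df$pos <- seq_len(nrow(df))
  if (anyNA(df$beta_hat) || anyNA(df$var) || any(!is.finite(df$beta_hat)) ||
      any(!is.finite(df$var)))
    stop("summary_table: non-finite beta_hat or var")
  if (any(df$var <= 0)) stop("summary_table: var must be positive")
  if (!("z" %in% names(df))) df$z <- df$beta_hat / sqrt(df$var)
  if (!("p" %in% names(df))) df$p <- 2 * pnorm(-abs(df$z))
  if (any(df$p <= 0 | df$p > 1)) stop("summary_table: p must lie in (0, 1]")
  bad_z <- abs(df$z - df$beta_hat / sqrt(df$var)) / pmax(abs(df$z), 1) > 0.01
  if (any(bad_z))
    stop("summary_table: z inconsistent with beta_hat/sqrt(var) beyond 1% for ",
         sum(bad_z), " row(s)")
  nz <- df$z != 0 & df$beta_hat != 0
  if (any(sign(df$z[nz]) != sign(df$beta_hat[nz])))
    stop("summary_table: sign(z) disagrees with sign(beta_hat)")
  if (anyDuplicated(df$snp_id)) stop("summary_table: duplicate snp_id")
  rownames(df) <- NULL
  structure(df, provenance = provenance,
            class = c("spebf_summary", "data.frame"))
}

#' @export
print.spebf_summary <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat("GWAS summary-statistics table:", nrow(x), "SNPs\n")
  if (!is.null(prov$path)) cat("  source:", prov$path, "\n")
  if (!is.null(prov$drops) && sum(unlist(prov$drops)) > 0) {
    d <- unlist(prov$drops)
    cat("  QC drops:", paste(sprintf("%s=%d", names(d), d), collapse = ", "), "\n")
  }
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Signed z from a two-sided P value
#'
#' Inverts the two-sided Wald P value, `p = 2 * pnorm(-|z|)`, using the
#' upper-tail normal quantile directly so that extreme tails (P down to
#' 1e-300, routine in GWAS) are handled without `1 - p` cancellation.
#'
#' @param p_two_sided two-sided P value(s) in (0, 1).
#' @param sign +1 or -1 (recycled): the sign of the effect estimate.
#' @return `sign * qnorm(p/2, lower.tail = FALSE)`.
#' @examples
#' z_from_p(0.05, 1)        # 1.959964
#' z_from_p(6.97e-10, -1)   # -6.166768
#' @export
z_from_p <- function(p_two_sided, sign = 1) {
  if (any(!is.finite(p_two_sided)) || any(p_two_sided <= 0) || any(p_two_sided >= 1))
    stop("z_from_p: p must lie strictly in (0, 1)")
  if (!all(sign %in% c(-1, 1))) stop("z_from_p: sign must be +1 or -1")
  sign * qnorm(p_two_sided / 2, lower.tail = FALSE)
}

#' Reconstruct the variance of beta-hat from its P value
#'
#' Inverts the Wald statistic: with `z` recovered from the two-sided P,
#' `V = (beta_hat / z)^2`.  Used when a summary file reports neither a
#' standard error nor a variance.
#'
#' @param beta_hat nonzero effect estimate(s), log odds ratio units.
#' @param p_two_sided two-sided P value(s) in (0, 1).
#' @return Positive variance(s) of `beta_hat`.
#' @export
derive_var_from_p <- function(beta_hat, p_two_sided) {
  if (any(beta_hat == 0))
    stop("derive_var_from_p: beta_hat = 0 leaves the variance undefined; ",
         "supply se or var directly")
  z <- z_from_p(p_two_sided, sign = ifelse(beta_hat >= 0, 1, -1))
  (beta_hat / z)^2
}

# resolve one logical column against the file header; NULL when unmapped/absent
.resolve_col <- function(dat, column_map, key) {
  nm <- column_map[[key]]
  if (is.null(nm) || !(nm %in% names(dat))) return(NULL)
  dat[[nm]]
}

#' Read and harmonize a GWAS summary-statistics file
#'
#' Reads a whitespace/tab-delimited text file with a header row (PGC
#' "daner"-style) and harmonizes it into a [summary_table()].  The effect
#' may be given as a log odds ratio (`beta`) or an odds ratio (`or`, taken
#' through `log`).  The variance source precedence is se > var >
#' reconstruction from (beta, p); when both se and var are present and
#' disagree by more than 5\% relative, a warning is issued and se wins.
#' Rows failing QC are dropped and counted per category in the returned
#' table's provenance.
#'
#' @param path file path.
#' @param column_map named list mapping logical names
#'   (`snp_id`, `chrom`, `pos`, `beta`, `or`, `se`, `var`, `p`, `maf`)
#'   to file column names.  Defaults follow the daner convention.
#' @param qc a [qc_options()] object.
#' @return A `spebf_summary` table; provenance records the path, the
#'   resolved column map, raw/retained row counts and per-category drops.
#' @export
read_summary <- function(path,
                         column_map = list(snp_id = "SNP", chrom = "CHR",
                                           pos = "BP", or = "OR", se = "SE",
                                           p = "P", maf = "FRQ_U"),
                         qc = qc_options()) {
  if (!file.exists(path)) stop("read_summary: no such file: ", path)
  dat <- read.table(path, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "#")
  n_raw <- nrow(dat)
  if (n_raw == 0L) stop("read_summary: file has no data rows: ", path)

  snp_id <- .resolve_col(dat, column_map, "snp_id")
  if (is.null(snp_id))
    stop("read_summary: column_map does not resolve required column 'snp_id'")
  snp_id <- as.character(snp_id)

  beta <- .resolve_col(dat, column_map, "beta")
  or_col <- .resolve_col(dat, column_map, "or")
  if (is.null(beta)) {
    if (is.null(or_col))
      stop("read_summary: column_map resolves neither 'beta' nor 'or'")
    beta <- suppressWarnings(log(as.numeric(or_col)))
  } else beta <- as.numeric(beta)

  se <- .resolve_col(dat, column_map, "se")
  va <- .resolve_col(dat, column_map, "var")
  pv <- .resolve_col(dat, column_map, "p")
  if (is.null(se) && is.null(va) && is.null(pv))
    stop("read_summary: column_map resolves none of 'se', 'var', 'p'")
  if (!is.null(se)) se <- as.numeric(se)
  if (!is.null(va)) va <- as.numeric(va)
  if (!is.null(pv)) pv <- as.numeric(pv)

  maf <- .resolve_col(dat, column_map, "maf")
  if (!is.null(maf)) {
    maf <- as.numeric(maf)
    maf <- pmin(maf, 1 - maf)  # fold allele frequency to MAF
  }
  chrom <- .resolve_col(dat, column_map, "chrom")
  chrom <- if (is.null(chrom)) rep("NA", n_raw) else as.character(chrom)
  pos <- .resolve_col(dat, column_map, "pos")
  pos <- if (is.null(pos)) seq_len(n_raw) else as.integer(pos)

  # variance precedence: se > var > (beta, p)
  v <- rep(NA_real_, n_raw)
  if (!is.null(se)) {
    v <- se^2
    if (!is.null(va)) {
      both <- is.finite(v) & is.finite(va) & va > 0
      conflict <- both & abs(v - va) / pmax(va, .Machine$double.eps) > 0.05
      if (any(conflict))
        warning("read_summary: se^2 and var disagree by >5% for ",
                sum(conflict), " row(s); se wins")
    }
  } else if (!is.null(va)) {
    v <- va
  }
  need_p_recon <- !is.finite(v) | v <= 0
  if (any(need_p_recon) && !is.null(pv)) {
    ok <- need_p_recon & is.finite(beta) & beta != 0 &
      is.finite(pv) & pv > 0 & pv < 1
    if (any(ok)) v[ok] <- derive_var_from_p(beta[ok], pv[ok])
  }

  drops <- c(missing_essential = 0L, nonfinite = 0L, invalid_p = 0L,
             low_maf = 0L, duplicate = 0L)
  keep <- rep(TRUE, n_raw)

  bad <- !is.finite(beta) | !is.finite(v) | v <= 0
  drops["missing_essential"] <- sum(bad & keep)
  keep <- keep & !bad

  if (!is.null(pv)) {
    badp <- is.finite(pv) & (pv <= 0 | pv > 1)
    drops["invalid_p"] <- sum(badp & keep)
    keep <- keep & !badp
  }
  if (!is.null(maf)) {
    badm <- is.finite(maf) & maf < qc$maf_min
    drops["low_maf"] <- sum(badm & keep)
    keep <- keep & !badm
  }
  dup <- duplicated(snp_id)
  drops["duplicate"] <- sum(dup & keep)
  keep <- keep & !dup

  for (cat in names(drops))
    if (drops[cat] > 0L)
      warning(sprintf("read_summary: dropped %d row(s): %s", drops[cat], cat))
  if (!any(keep)) stop("read_summary: no rows remain after QC")

  beta <- beta[keep]; v <- v[keep]
  z <- beta / sqrt(v)
  # exact z from p where variance was reconstructed from p
  p_out <- if (!is.null(pv)) {
    pk <- pv[keep]
    ifelse(is.finite(pk) & pk > 0 & pk <= 1, pk, 2 * pnorm(-abs(z)))
  } else 2 * pnorm(-abs(z))

  df <- data.frame(snp_id = snp_id[keep], chrom = chrom[keep], pos = pos[keep],
                   beta_hat = beta, var = v, z = z, p = p_out,
                   stringsAsFactors = FALSE)
  if (!is.null(maf)) df$maf <- maf[keep]
  summary_table(df, provenance = list(
    path = path, column_map = column_map, n_raw = n_raw,
    n_retained = sum(keep), drops = as.list(drops)))
}

#' Write a summary table losslessly
#'
#' Full-precision (15 significant digits) tab-separated output whose columns
#' (`SNP`, `CHR`, `BP`, `BETA`, `VAR`, `P`, `MAF`) round-trip through
#' [read_summary()] with `column_map = summary_column_map()`.
#'
#' @param table a `spebf_summary` table.
#' @param path output path.
#' @export
write_summary <- function(table, path) {
  stopifnot(inherits(table, "spebf_summary"))
  out <- data.frame(SNP = table$snp_id, CHR = table$chrom, BP = table$pos,
                    BETA = format(table$beta_hat, digits = 15, trim = TRUE),
                    VAR = format(table$var, digits = 15, trim = TRUE),
                    P = format(table$p, digits = 15, trim = TRUE),
                    stringsAsFactors = FALSE)
  if (!is.null(table$maf))
    out$MAF <- format(table$maf, digits = 15, trim = TRUE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Column map matching [write_summary()] output
#' @return A named list usable as `column_map` in [read_summary()].
#' @export
summary_column_map <- function() {
  list(snp_id = "SNP", chrom = "CHR", pos = "BP", beta = "BETA",
       var = "VAR", p = "P", maf = "MAF")
}

#' Write a per-SNP Bayes-factor results table
#'
#' Tab-separated output with the fixed header `snp_id chrom pos beta_hat var
#' z p abf log10_abf spebf log10_spebf post_null_prob rank_p rank_abf
#' rank_spebf`; floating values at 6 significant digits, rows in input order.
#'
#' @param table a `bf_table` from [rank_table()].
#' @param path output path.
#' @param decisions optional logical vector from [decide()]; when supplied an
#'   extra `reject` column is appended after the fixed schema.
#' @export
write_results <- function(table, path, decisions = NULL) {
  stopifnot(inherits(table, "spebf_bf_table"))
  if (nrow(table) == 0L) stop("write_results: empty table")
  cols <- c("snp_id", "chrom", "pos", "beta_hat", "var", "z", "p", "abf",
            "log10_abf", "spebf", "log10_spebf", "post_null_prob",
            "rank_p", "rank_abf", "rank_spebf")
  out <- as.data.frame(table)[, cols]
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x) format(x, digits = 6, trim = TRUE))
  if (!is.null(decisions)) {
    stopifnot(is.logical(decisions), length(decisions) == nrow(table))
    out$reject <- decisions
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read back a results table written by [write_results()]
#' @param path file path.
#' @return A `bf_table` data.frame.
#' @export
read_results <- function(path) {
  dat <- read.table(path, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
  dat$chrom <- as.character(dat$chrom)
  dat$snp_id <- as.character(dat$snp_id)
  structure(dat, class = c("spebf_bf_table", "data.frame"))
}
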