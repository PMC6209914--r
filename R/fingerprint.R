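# Core fingerprinting: filtering, the rsid-mod-L column hash, raw
# fingerprints (per-SNP-frequency and cohort-expectation modes) and the
# two-pass normalization.

#' Construct a fingerprint object
#'
#' A genotype fingerprint is a 4 x L real matrix (rows A, C, G, T; columns
#' indexed 0..L-1 by rsid mod L) plus metadata. Users normally obtain
#' fingerprints from [raw_fingerprint_freq()] or [raw_fingerprints_cohort()]
#' rather than calling this constructor.
#'
#' @param values 4 x L numeric matrix.
#' @param state one of `"raw"`, `"normalized"`, `"population"`, `"adjusted"`.
#' @param panel panel tag or `NA`.
#' @param n_snps number of SNPs tallied.
#' @param id optional individual identifier carried through comparisons.
#' @return An object of class `genofp`.
#' @export
new_fingerprint <- function(values, state = "raw", panel = NA_character_,
                            n_snps = 0L, id = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != 4) stop("fingerprint values must have 4 rows (A,C,G,T)")
  if (ncol(values) < 1) stop("fingerprint must have at least one column")
  if (!state %in% c("raw", "normalized", "population", "adjusted"))
    stop("invalid fingerprint state '", state, "'")
  rownames(values) <- NUCS
  structure(list(values = values, L = ncol(values), state = state,
                 panel = panel, n_snps = as.integer(n_snps), id = id),
            class = "genofp")
}

#' @export
print.genofp <- function(x, ...) {
  cat("genotype fingerprint", if (!is.null(x$id)) paste0("'", x$id, "'"),
      "\n  L =", x$L, " state =", x$state,
      " n_snps =", x$n_snps,
      if (!is.na(x$panel)) paste(" panel =", x$panel), "\n")
  if (identical(x$state, "population"))
    cat("  population =", x$population, " n_members =", x$n_members, "\n")
  invisible(x)
}

#' Fingerprint column for an rsid
#'
#' The locality-sensitive hash at the heart of the method: a SNP is tallied
#' in column `rsid mod L` (0-based). At the default L = 1000, rs1801133
#' lands in column 133.
#'
#' @param rsid_number numeric vector of rsid numbers.
#' @param L fingerprint length (number of columns), at least 1.
#' @return Integer-valued vector of 0-based column indices.
#' @export
column_of <- function(rsid_number, L) {
  if (length(L) != 1 || is.na(L) || L < 1 || L != floor(L))
    stop("L must be a positive integer")
  rsid_number %% L
}

#' Filter calls to autosomal, complete, ACGT-only biallelic SNPs
#'
#' Retains calls that are autosomal (chromosomes 1-22), carry exactly two
#' observed alleles, with both alleles in A/C/G/T; optionally restricted to
#' a panel. Sex chromosomes are excluded because allele counts differ
#' between sexes; indel symbols (I/D) and '-' are excluded because their
#' reporting conventions vary across assays. Order is preserved.
#'
#' @param calls a [snp_calls] data frame.
#' @param pan optional [panel]; if given, only rsids in the panel are kept.
#' @return Filtered [snp_calls] with attribute `filter_counts`, a named
#'   vector of rejection counts
#'   (`non_autosomal`, `incomplete`, `non_acgt`, `not_in_panel`).
#' @export
filter_calls <- function(calls, pan = NULL) {
  auto <- calls$chrom %in% AUTOSOMES
  complete <- n_alleles(calls) == 2L
  acgt <- !is.na(calls$a1) & !is.na(calls$a2) &
    calls$a1 %in% NUCS & calls$a2 %in% NUCS
  in_panel <- if (is.null(pan)) rep(TRUE, nrow(calls))
              else calls$rsid %in% pan$rsids
  keep <- auto & complete & acgt & in_panel
  counts <- c(non_autosomal = sum(!auto),
              incomplete = sum(auto & !complete),
              non_acgt = sum(auto & complete & !acgt),
              not_in_panel = sum(auto & complete & acgt & !in_panel))
  out <- calls[keep, , drop = FALSE]
  attr(out, "filter_counts") <- counts
  attr(out, "skip_counts") <- attr(calls, "skip_counts")
  out
}

# observed allele-count matrix: one row per call, columns A,C,G,T
obs_counts <- function(calls) {
  m <- vapply(NUCS, function(x)
    (!is.na(calls$a1) & calls$a1 == x) + (!is.na(calls$a2) & calls$a2 == x),
    numeric(nrow(calls)))
  if (nrow(calls) == 1L) m <- matrix(m, nrow = 1, dimnames = list(NULL, NUCS))
  m
}

# drop duplicated rsids, keeping the first occurrence
dedupe_rsids <- function(calls, id = NULL) {
  dup <- duplicated(calls$rsid)
  if (any(dup)) {
    warning(sum(dup), " duplicate rsid(s) dropped",
            if (!is.null(id)) paste0(" for individual '", id, "'"),
            " (first occurrence kept)")
    calls <- calls[!dup, , drop = FALSE]
  }
  calls
}

# scatter per-call 4-vectors into a 4 x L matrix by rsid mod L
tally_columns <- function(contrib, rsid, L) {
  if (length(rsid) == 0) return(matrix(0, 4, L))
  col <- rsid %% L
  agg <- rowsum(contrib, group = col)               # rows sorted by column
  values <- matrix(0, 4, L)
  values[, as.integer(rownames(agg)) + 1L] <- t(agg)
  values
}

#' Raw fingerprint from per-SNP allele frequencies
#'
#' For each filtered call, counts observed nucleotides (n_A..n_T with
#' n_N = 2), subtracts the expected counts `2 * f_X` from a known
#' frequency table, and accumulates the differences in column
#' `rsid mod L`. Every column of the result sums to zero, since observed
#' and expected totals both equal 2 per SNP.
#'
#' @param calls filtered [snp_calls] (see [filter_calls()]); all calls must
#'   carry exactly two A/C/G/T alleles.
#' @param L fingerprint length; default 1000.
#' @param freqs a [frequency_table] covering the calls' rsids; calls with
#'   rsids absent from the table are skipped with a warning.
#' @param panel_name optional panel tag recorded in metadata.
#' @param id optional individual identifier.
#' @return A `genofp` fingerprint with `state = "raw"`.
#' @export
raw_fingerprint_freq <- function(calls, L = 1000, freqs,
                                 panel_name = NA_character_, id = NULL) {
  stopifnot(inherits(freqs, "freq_table"))
  if (L < 1 || L != floor(L)) stop("L must be a positive integer")
  if (any(n_alleles(calls) != 2L) ||
      any(!calls$a1 %in% NUCS) || any(!calls$a2 %in% NUCS))
    stop("all calls must have exactly two A/C/G/T alleles; run filter_calls()")
  calls <- dedupe_rsids(calls, id)

  idx <- match(calls$rsid, freqs$rsid)
  miss <- is.na(idx)
  if (any(miss)) {
    warning(sum(miss), " call(s) with rsid absent from frequency table skipped")
    calls <- calls[!miss, , drop = FALSE]
    idx <- idx[!miss]
  }
  if (nrow(calls) == 0)
    return(new_fingerprint(matrix(0, 4, L), "raw", panel_name, 0L, id))

  fm <- as.matrix(freqs[idx, c("f_A", "f_C", "f_G", "f_T")])
  dev <- abs(rowSums(fm) - 1)
  if (any(dev > 1e-6))
    stop("frequencies for rs", calls$rsid[which.max(dev)], " do not sum to 1")

  contrib <- obs_counts(calls) - 2 * fm
  values <- tally_columns(contrib, calls$rsid, L)
  new_fingerprint(values, "raw", panel_name, nrow(calls), id)
}

#' Raw fingerprints for a cohort via pooled column expectations
#'
#' The cohort variant: allele counts are tallied per individual into a
#' 4 x L matrix N_X with column totals N_N = 2k (k = SNPs assigned to the
#' column); pooled across individuals they give expected column
#' frequencies E(f_X), and each individual's raw fingerprint is
#' `t_X = N_X - N_N * E(f_X)`. No external frequency source is needed.
#' When all individuals cover the identical SNP set, the fingerprints sum
#' to the zero matrix across the cohort.
#'
#' @param cohort named list of filtered [snp_calls], one per individual;
#'   at least two individuals.
#' @param L fingerprint length; default 1000.
#' @param panel_name optional panel tag recorded in metadata.
#' @return A list with elements `fingerprints` (named list of raw `genofp`
#'   objects) and `tallies` (per-individual count matrices `counts`,
#'   per-individual column totals `totals`, and the pooled expected
#'   frequencies `expected_freq`, a 4 x L matrix).
#' @export
raw_fingerprints_cohort <- function(cohort, L = 1000,
                                    panel_name = NA_character_) {
  if (length(cohort) < 2)
    stop("cohort mode needs at least 2 individuals (expectation undefined)")
  if (is.null(names(cohort)) || any(!nzchar(names(cohort))))
    stop("cohort must be a named list of snp_calls")
  if (L < 1 || L != floor(L)) stop("L must be a positive integer")

  ids <- names(cohort)
  counts <- vector("list", length(cohort)); names(counts) <- ids
  nsnp <- integer(length(cohort))
  for (i in seq_along(cohort)) {
    calls <- cohort[[i]]
    if (any(n_alleles(calls) != 2L) ||
        any(!calls$a1 %in% NUCS) || any(!calls$a2 %in% NUCS))
      stop("calls for '", ids[i],
           "' must have exactly two A/C/G/T alleles; run filter_calls()")
    calls <- dedupe_rsids(calls, ids[i])
    counts[[i]] <- tally_columns(obs_counts(calls), calls$rsid, L)
    nsnp[i] <- nrow(calls)
  }
  totals <- lapply(counts, colSums)                    # N_N per column
  pooled <- Reduce(`+`, counts)
  pooled_tot <- Reduce(`+`, totals)
  ef <- matrix(0, 4, L)
  nz <- pooled_tot > 0
  ef[, nz] <- sweep(pooled[, nz, drop = FALSE], 2, pooled_tot[nz], "/")

  fps <- lapply(seq_along(cohort), function(i) {
    expected <- sweep(ef, 2, totals[[i]], "*")         # N_N * E[f_X]
    new_fingerprint(counts[[i]] - expected, "raw", panel_name,
                    nsnp[i], ids[i])
  })
  names(fps) <- ids
  rownames(ef) <- NUCS
  list(fingerprints = fps,
       tallies = list(counts = counts, totals = totals, expected_freq = ef))
}

#' Normalize a raw fingerprint
#'
#' Two z-scoring passes: first each column (4 entries) has its mean
#' subtracted and is divided by its standard deviation, mitigating
#' differences in substitution-type composition between columns; then each
#' row (L entries) likewise, mitigating residual methodological differences
#' between rows. Standard deviations are population-style (divide by n).
#' Degenerate columns/rows (sd = 0) are centered but not divided, so an
#' all-zero fingerprint normalizes to all zeros. After normalization every
#' non-degenerate row has mean 0 and sd 1.
#'
#' @param fp a raw `genofp` fingerprint with L >= 2.
#' @return A `genofp` with `state = "normalized"`.
#' @export
normalize_fingerprint <- function(fp) {
  stopifnot(inherits(fp, "genofp"))
  if (fp$L < 2) stop("normalization requires L >= 2")
  v <- fp$values
  # pass 1: columns
  v <- sweep(v, 2, colMeans(v))
  s <- sqrt(colMeans(v^2))
  nz <- s > 0
  v[, nz] <- sweep(v[, nz, drop = FALSE], 2, s[nz], "/")
  # pass 2: rows
  v <- v - rowMeans(v)
  rs <- sqrt(rowMeans(v^2))
  nzr <- rs > 0
  v[nzr, ] <- v[nzr, , drop = FALSE] / rs[nzr]
  out <- new_fingerprint(v, "normalized", fp$panel, fp$n_snps, fp$id)
  out
}
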