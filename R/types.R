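#' @keywords internal
"_PACKAGE"

# Nucleotide row order used by every 4 x L fingerprint in the package.
NUCS <- c("A", "C", "G", "T")

# Symbols that may appear in a DTC genotype string. I/D (insertion/deletion)
# and '-' survive parsing; filter_calls() removes them.
ALLELE_SYMBOLS <- c("A", "C", "G", "T", "I", "D", "-")

AUTOSOMES <- as.character(1:22)

#' Construct a table of SNP calls
#'
#' A `snp_calls` object is a data frame with one row per observed genotype
#' call: the numeric part of the dbSNP rsid, chromosome label, 1-based
#' position, and up to two observed allele symbols (`NA` for a missing
#' allele; both `NA` for a no-call).
#'
#' @param rsid numeric vector of positive rsid numbers (the digits of
#'   "rsNNN").
#' @param chrom character vector of chromosome labels (`"1"`..`"22"`, `"X"`,
#'   `"Y"`, `"MT"`).
#' @param pos numeric vector of 1-based positions.
#' @param a1,a2 character vectors of allele symbols from
#'   `A,C,G,T,I,D,-` or `NA`.
#' @return A data frame of class `snp_calls`.
#' @export
snp_calls <- function(rsid, chrom, pos, a1, a2) {
  n <- length(rsid)
  stopifnot(length(chrom) == n, length(pos) == n,
            length(a1) == n, length(a2) == n)
  if (n > 0 && (any(is.na(rsid)) || any(rsid <= 0) || any(rsid != floor(rsid))))
    stop("rsid numbers must be positive integers")
  bad <- function(a) !is.na(a) & !(a %in% ALLELE_SYMBOLS)
  if (any(bad(a1)) || any(bad(a2)))
    stop("allele symbols must be one of ", paste(ALLELE_SYMBOLS, collapse = ","))
  structure(
    data.frame(rsid = as.numeric(rsid), chrom = as.character(chrom),
               pos = as.numeric(pos), a1 = as.character(a1),
               a2 = as.character(a2), stringsAsFactors = FALSE),
    class = c("snp_calls", "data.frame"))
}

# number of observed alleles per call (0, 1 or 2)
n_alleles <- function(calls) {
  (!is.na(calls$a1)) + (!is.na(calls$a2))
}

#' Construct an rsid panel
#'
#' A panel is the set of rsids assayed by one array design (e.g., the
#' 23andMe V2 or V3 chips). Fingerprints restricted to a panel remain
#' comparable across designs that share rsids.
#'
#' @param name short tag for the design (e.g., `"V3"`).
#' @param rsids numeric vector of positive rsid numbers; duplicates removed.
#' @return An object of class `panel`.
#' @export
panel <- function(name, rsids) {
  rsids <- unique(as.numeric(rsids))
  if (length(rsids) == 0) stop("panel must contain at least one rsid")
  if (any(is.na(rsids)) || any(rsids <= 0) || any(rsids != floor(rsids)))
    stop("panel rsids must be positive integers")
  structure(list(name = as.character(name), rsids = sort(rsids)),
            class = "panel")
}

#' @export
print.panel <- function(x, ...) {
  cat("rsid panel '", x$name, "': ", length(x$rsids), " rsids\n", sep = "")
  invisible(x)
}

#' Construct a per-rsid allele-frequency table
#'
#' Expected nucleotide frequencies per rsid, used by the per-SNP-frequency
#' fingerprint mode. Frequencies are indexed by nucleotide (not ref/alt) so
#' allele-order conventions of source files cannot flip tally signs. Each
#' row must satisfy `f_A + f_C + f_G + f_T = 1` within 1e-6.
#'
#' @param rsid numeric vector of rsid numbers.
#' @param f_A,f_C,f_G,f_T numeric frequency vectors in `[0, 1]`.
#' @return A data frame of class `freq_table`.
#' @export
frequency_table <- function(rsid, f_A, f_C, f_G, f_T) {
  ft <- data.frame(rsid = as.numeric(rsid), f_A = f_A, f_C = f_C,
                   f_G = f_G, f_T = f_T)
  fm <- as.matrix(ft[, c("f_A", "f_C", "f_G", "f_T")])
  if (any(fm < 0) || any(fm > 1))
    stop("allele frequencies must lie in [0, 1]")
  dev <- abs(rowSums(fm) - 1)
  if (any(dev > 1e-6))
    stop("allele frequencies for rs", ft$rsid[which.max(dev)],
         " do not sum to 1 (deviation ", signif(max(dev), 3), ")")
  if (anyDuplicated(ft$rsid))
    stop("duplicate rsid in frequency table")
  class(ft) <- c("freq_table", "data.frame")
  ft
}
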