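# KING-robust kinship: the allele-sharing estimator used as an independent
# baseline against which population-adjusted fingerprint correlations are
# validated. The between-family variant is implemented, as appropriate for
# a cohort of nominally unrelated individuals.

#' KING-robust kinship coefficient for a pair of individuals
#'
#' Estimates the kinship coefficient phi from two aligned 0/1/2 dosage
#' vectors as
#' `phi = (N_het,het - 2 * N_opp,hom) / (N_het_i + N_het_j)`,
#' where `N_het,het` counts SNPs heterozygous in both individuals,
#' `N_opp,hom` counts SNPs with opposite homozygotes, and `N_het_i` counts
#' heterozygous SNPs in individual i. SNPs missing in either individual are
#' excluded. Expectations: 0.5 for self/identical twins, 0.25 for
#' parent-offspring and full siblings, 0.125 for second-degree relatives,
#' 0 for unrelated pairs. The estimator depends only on joint-heterozygosity
#' and opposite-homozygote counts, so 0/1/2 allele-labeling choices cannot
#' flip the result.
#'
#' @param a,b numeric vectors of genotypes in `{0, 1, 2, NA}`, aligned on
#'   the same SNP set.
#' @param id_a,id_b optional identifiers carried into the result.
#' @return List with `phi` (`NA` when no heterozygous sites exist in either
#'   individual), `defined` (logical), `n_used`, `n_het_a`, `n_het_b`,
#'   `n_het_het`, `n_opp_hom`, `id_a`, `id_b`.
#' @export
king_robust <- function(a, b, id_a = NA_character_, id_b = NA_character_) {
  if (length(a) != length(b))
    stop("genotype vectors must have equal length")
  ok_vals <- function(x) all(x[!is.na(x)] %in% c(0, 1, 2))
  if (!ok_vals(a) || !ok_vals(b))
    stop("genotypes must be 0, 1, 2 or NA")
  use <- !is.na(a) & !is.na(b)
  a <- a[use]; b <- b[use]
  het_a <- sum(a == 1)
  het_b <- sum(b == 1)
  het_het <- sum(a == 1 & b == 1)
  opp <- sum(abs(a - b) == 2)
  denom <- het_a + het_b
  list(phi = if (denom > 0) (het_het - 2 * opp) / denom else NA_real_,
       defined = denom > 0,
       n_used = length(a), n_het_a = het_a, n_het_b = het_b,
       n_het_het = het_het, n_opp_hom = opp, id_a = id_a, id_b = id_b)
}

#' KING-robust kinship for all pairs in a dosage matrix
#'
#' @param dosage individuals x SNPs matrix of 0/1/2 genotypes (`NA`
#'   allowed), rownames used as identifiers.
#' @return Data frame with columns `id_a`, `id_b`, `phi`, `n_used`, one row
#'   per unordered pair.
#' @export
king_robust_all <- function(dosage) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage)
  if (n < 2) stop("need at least two individuals")
  ids <- rownames(dosage)
  if (is.null(ids)) ids <- paste0("ind", seq_len(n))
  pairs <- utils::combn(n, 2)
  out <- apply(pairs, 2, function(p) {
    k <- king_robust(dosage[p[1], ], dosage[p[2], ])
    c(phi = k$phi, n_used = k$n_used)
  })
  data.frame(id_a = ids[pairs[1, ]], id_b = ids[pairs[2, ]],
             phi = out["phi", ], n_used = as.integer(out["n_used", ]),
             stringsAsFactors = FALSE)
}
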