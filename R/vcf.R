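#' Extract panel genotypes from a VCF file
#'
#' Reads a VCF (via vcfR) and converts, for each sample, every biallelic SNP
#' record whose ID is in the panel into a [snp_calls] row, translating GT
#' indices through REF/ALT to nucleotide symbols. Missing genotypes
#' (`./.`) become no-calls. Records absent from the panel, multi-allelic
#' records, and non-SNP records are skipped. Output is sorted by rsid
#' number, so it is invariant under record reordering in the file.
#'
#' @param path path to a VCF (v4.x) file.
#' @param pan a [panel] restricting the rsids extracted.
#' @return Named list mapping sample id to a [snp_calls] data frame.
#' @export
extract_from_vcf <- function(path, pan) {
  stopifnot(inherits(pan, "panel"))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (nrow(fix) == 0) return(list())

  id <- fix[, "ID"]
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  is_rs <- grepl("^rs[0-9]+$", id)
  rsnum <- rep(NA_real_, length(id))
  rsnum[is_rs] <- as.numeric(sub("^rs", "", id[is_rs]))
  snp <- ref %in% NUCS & alt %in% NUCS          # biallelic SNP, single ALT
  keep <- is_rs & snp & rsnum %in% pan$rsids
  if (!any(keep)) {
    samples <- colnames(vcf@gt)[-1]
    empty <- snp_calls(numeric(0), character(0), numeric(0),
                       character(0), character(0))
    return(stats::setNames(rep(list(empty), length(samples)), samples))
  }

  gt <- vcfR::extract.gt(vcf, element = "GT")[keep, , drop = FALSE]
  rsnum <- rsnum[keep]
  chrom <- norm_chrom(fix[keep, "CHROM"])
  pos <- as.numeric(fix[keep, "POS"])
  ref <- ref[keep]
  alt <- alt[keep]

  ord <- order(rsnum)
  translate <- function(g) {
    # g: character vector of GT strings for one sample, aligned with records
    a <- matrix(NA_character_, length(g), 2)
    parts <- strsplit(g, "[/|]")
    for (i in seq_along(parts)) {
      p <- parts[[i]]
      if (length(p) == 0 || is.na(g[i])) next
      al <- vapply(p[1:min(2, length(p))], function(x)
        switch(x, "0" = ref[i], "1" = alt[i], NA_character_), "")
      a[i, seq_along(al)] <- al
    }
    a
  }
  out <- lapply(colnames(gt), function(s) {
    a <- translate(gt[, s])
    calls <- snp_calls(rsnum, chrom, pos, a[, 1], a[, 2])
    calls[ord, , drop = FALSE]
  })
  stats::setNames(out, colnames(gt))
}
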