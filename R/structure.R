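# Population-structure analysis: PCA on stacked fingerprints, and the
# classical baseline PCA on a MAF-filtered, LD-pruned 0/1/2 genotype matrix.

#' Construct a genotype dosage matrix
#'
#' Individuals x SNPs matrix of minor-allele counts (0/1/2; `NA` = missing)
#' with per-column rsid, chromosome and position; columns must be sorted by
#' (chromosome, position).
#'
#' @param dosage numeric matrix, individuals in rows.
#' @param rsid,chrom,pos per-column metadata; `chrom` integer 1-22.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, rsid, chrom, pos) {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  stopifnot(length(rsid) == m, length(chrom) == m, length(pos) == m)
  vals <- dosage[!is.na(dosage)]
  if (any(!vals %in% c(0, 1, 2)))
    stop("dosage entries must be 0, 1, 2 or NA")
  chrom <- as.integer(chrom)
  if (m > 0 && !identical(order(chrom, pos), seq_len(m)))
    stop("columns must be sorted by (chromosome, position)")
  structure(list(dosage = dosage, rsid = as.numeric(rsid),
                 chrom = chrom, pos = as.numeric(pos)),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("genotype matrix:", nrow(x$dosage), "individuals x",
      ncol(x$dosage), "SNPs\n")
  invisible(x)
}

#' Stack fingerprints into a data matrix
#'
#' One row per individual, columns the flattened (rows-concatenated)
#' fingerprint, so the matrix is individuals x 4L.
#'
#' @param fps named list of `genofp` fingerprints sharing L and state.
#' @return Numeric matrix with individuals as rownames.
#' @export
fingerprint_matrix <- function(fps) {
  if (length(fps) == 0) stop("need at least one fingerprint")
  Ls <- vapply(fps, function(f) f$L, numeric(1))
  states <- vapply(fps, function(f) f$state, character(1))
  if (length(unique(Ls)) != 1)
    stop("mixed fingerprint lengths: ", paste(unique(Ls), collapse = ", "))
  if (length(unique(states)) != 1)
    stop("mixed fingerprint states: ", paste(unique(states), collapse = ", "))
  x <- t(vapply(fps, flatten_fp, numeric(4 * Ls[1])))
  rownames(x) <- names(fps)
  x
}

#' Principal components analysis of a data matrix
#'
#' Centered, unit-variance-scaled PCA via singular value decomposition
#' (`stats::prcomp`). Constant columns are dropped beforehand (scaling
#' would divide by zero) and counted. For test stability each component's
#' sign is fixed so that its largest-magnitude loading is positive.
#'
#' @param x numeric matrix, individuals in rows (either a stacked
#'   fingerprint matrix or a `geno_matrix` dosage matrix).
#' @param k number of components to retain (default all).
#' @return List of class `genofp_pca`: `scores` (individuals x components),
#'   `explained` (non-increasing variance fractions), `rotation`, `sdev`,
#'   and `n_constant_dropped`.
#' @export
fp_pca <- function(x, k = NULL) {
  if (inherits(x, "geno_matrix")) x <- x$dosage
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("PCA needs at least 2 rows")
  v <- colMeans(x^2) - colMeans(x)^2
  keep <- v > 1e-12
  n_dropped <- sum(!keep)
  x <- x[, keep, drop = FALSE]
  if (ncol(x) == 0) stop("all columns are constant")
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  total_var <- sum(p$sdev^2)
  if (!is.null(k)) {
    k <- min(k, ncol(p$rotation))
    p$rotation <- p$rotation[, seq_len(k), drop = FALSE]
    p$x <- p$x[, seq_len(k), drop = FALSE]
    p$sdev <- p$sdev[seq_len(k)]
  }
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  structure(list(scores = p$x,
                 explained = p$sdev^2 / total_var,
                 rotation = p$rotation, sdev = p$sdev,
                 n_constant_dropped = n_dropped),
            class = "genofp_pca")
}

#' MAF filtering, LD pruning and random thinning of a genotype matrix
#'
#' Three passes, in order: (1) drop SNPs with minor-allele frequency below
#' `maf_min`; (2) scanning left to right within each chromosome, drop any
#' SNP in complete linkage disequilibrium (r^2 = 1: genotype vector
#' identical or perfectly anti-correlated) with the nearest retained SNP to
#' its left; (3) retain each surviving SNP independently with probability
#' `keep_fraction` under the given seed.
#'
#' @param gm a [geno_matrix].
#' @param maf_min minimum minor-allele frequency (default 0.05).
#' @param keep_fraction thinning probability (default 0.05); 1 disables
#'   thinning.
#' @param seed integer seed for the thinning pass.
#' @return Pruned [geno_matrix] with attribute `prune_counts`
#'   (`maf_dropped`, `ld_dropped`, `thin_dropped`) and attribute `seed`.
#' @export
maf_ld_prune <- function(gm, maf_min = 0.05, keep_fraction = 0.05, seed) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (missing(seed) && keep_fraction < 1)
    stop("thinning requires an explicit seed")
  d <- gm$dosage
  m <- ncol(d)

  f <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  keep1 <- !is.na(maf) & maf >= maf_min
  idx <- which(keep1)

  # pass 2: complete-LD pruning against nearest retained column to the left
  keep2 <- logical(length(idx))
  last <- -1L; last_chr <- NA_integer_
  for (j in seq_along(idx)) {
    cj <- idx[j]
    if (is.na(last_chr) || gm$chrom[cj] != last_chr) {
      keep2[j] <- TRUE
    } else {
      r <- suppressWarnings(stats::cor(d[, cj], d[, last],
                                       use = "complete.obs"))
      keep2[j] <- !(is.finite(r) && abs(r) >= 1 - 1e-9)
    }
    if (keep2[j]) { last <- cj; last_chr <- gm$chrom[cj] }
  }
  idx2 <- idx[keep2]

  # pass 3: random thinning
  if (keep_fraction < 1) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    keep3 <- stats::runif(length(idx2)) <= keep_fraction
  } else keep3 <- rep(TRUE, length(idx2))
  idx3 <- idx2[keep3]

  out <- geno_matrix(d[, idx3, drop = FALSE], gm$rsid[idx3],
                     gm$chrom[idx3], gm$pos[idx3])
  attr(out, "prune_counts") <- c(maf_dropped = m - length(idx),
                                 ld_dropped = length(idx) - length(idx2),
                                 thin_dropped = length(idx2) - length(idx3))
  attr(out, "seed") <- if (keep_fraction < 1) seed else NA_integer_
  out
}

#' Write PCA scores and explained variance to TSV files
#' @param pca a `genofp_pca` result.
#' @param scores_path,explained_path output paths (either may be `NULL`).
#' @return Invisibly, `NULL`.
#' @export
write_pca <- function(pca, scores_path = NULL, explained_path = NULL) {
  if (!is.null(scores_path)) {
    df <- data.frame(id = rownames(pca$scores), pca$scores)
    utils::write.table(df, scores_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(explained_path)) {
    df <- data.frame(component = seq_along(pca$explained),
                     explained = pca$explained)
    utils::write.table(df, explained_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(NULL)
}

#' Write a genotype matrix to TSV
#'
#' Format: two comment lines carrying per-SNP chromosome and position,
#' then a header row (`id` followed by `rsNNN` column names) and one row
#' of 0/1/2 dosages per individual (`NA` for missing).
#'
#' @param gm a [geno_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_geno_matrix <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#chrom", gm$chrom), collapse = "\t"), con)
  writeLines(paste(c("#pos", format(gm$pos, scientific = FALSE, trim = TRUE)),
                   collapse = "\t"), con)
  ids <- rownames(gm$dosage)
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(gm$dosage)))
  writeLines(paste(c("id", paste0("rs", format(gm$rsid, scientific = FALSE,
                                               trim = TRUE))),
                   collapse = "\t"), con)
  for (i in seq_len(nrow(gm$dosage)))
    writeLines(paste(c(ids[i], gm$dosage[i, ]), collapse = "\t"), con)
  invisible(path)
}

#' Read a genotype matrix written by [write_geno_matrix()]
#' @param path input path.
#' @return A [geno_matrix].
#' @export
read_geno_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  get_meta <- function(key) {
    hit <- grep(paste0("^#", key, "\t"), meta, value = TRUE)
    if (length(hit) == 0) stop("missing #", key, " line")
    strsplit(hit[1], "\t", fixed = TRUE)[[1]][-1]
  }
  chrom <- as.integer(get_meta("chrom"))
  pos <- as.numeric(get_meta("pos"))
  hdr <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  rsid <- as.numeric(sub("^rs", "", hdr[-1]))
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  ids <- vapply(rows, `[`, "", 1)
  d <- t(vapply(rows, function(r) suppressWarnings(as.numeric(r[-1])),
                numeric(length(rsid))))
  rownames(d) <- ids
  geno_matrix(d, rsid, chrom, pos)
}
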