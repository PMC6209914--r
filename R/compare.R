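# Fingerprint comparison by Spearman correlation of the flattened
# (rows-concatenated) 4L-vectors. Pre-ranking each fingerprint once makes
# all-against-all comparison a single matrix product of standardized ranks.

flatten_fp <- function(fp) as.vector(t(fp$values))  # row A, then C, G, T

# midranks of the flattened fingerprint, centered and scaled to unit norm;
# errors on constant vectors (Spearman undefined, and a constant fingerprint
# is always a usage error)
std_ranks <- function(fp, what = "fingerprint") {
  r <- rank(flatten_fp(fp))                          # average ranks for ties
  r <- r - mean(r)
  nrm <- sqrt(sum(r^2))
  if (nrm == 0)
    stop(what, if (!is.null(fp$id)) paste0(" '", fp$id, "'"),
         " is constant; Spearman correlation is undefined")
  r / nrm
}

check_comparable <- function(a, b, allow_raw) {
  stopifnot(inherits(a, "genofp"), inherits(b, "genofp"))
  if (a$L != b$L)
    stop("fingerprints have different lengths: L = ", a$L, " vs L = ", b$L)
  ok_states <- c("normalized", "adjusted", "population")
  if (!allow_raw && (!a$state %in% ok_states || !b$state %in% ok_states))
    stop("comparison of raw fingerprints requires allow_raw = TRUE")
}

#' Compare two fingerprints (Spearman's rho)
#'
#' Concatenates the rows of each 4 x L fingerprint into a 4L-vector and
#' computes the Spearman rank correlation between the two vectors
#' (Pearson correlation of midrank-transformed values). This is the
#' method's sole similarity measure: ~1 for the same individual, ~0.5
#' raw-scale for first-degree relatives after population adjustment,
#' near 0 for unrelated individuals.
#'
#' @param a,b `genofp` fingerprints with equal L, both normalized or
#'   adjusted (or population).
#' @param allow_raw compare raw fingerprints anyway (default `FALSE`).
#' @return One-row data frame with columns `id_a`, `id_b`, `rho`, `L`,
#'   `state_a`, `state_b`.
#' @export
fp_compare <- function(a, b, allow_raw = FALSE) {
  check_comparable(a, b, allow_raw)
  rho <- sum(std_ranks(a) * std_ranks(b))
  data.frame(id_a = if (is.null(a$id)) NA_character_ else a$id,
             id_b = if (is.null(b$id)) NA_character_ else b$id,
             rho = min(1, max(-1, rho)),
             L = a$L, state_a = a$state, state_b = b$state,
             stringsAsFactors = FALSE)
}

#' All-against-all fingerprint comparison
#'
#' Ranks each fingerprint once, then computes every pairwise Spearman
#' correlation as a dot product of standardized rank vectors — the reuse of
#' ranks is what makes large cohort screens fast. Emits each unordered
#' pair exactly once (n(n-1)/2 rows, no self-comparisons).
#'
#' @param fps named list of `genofp` fingerprints sharing L and state.
#' @param allow_raw compare raw fingerprints (default `FALSE`).
#' @return Data frame with columns `id_a`, `id_b`, `rho`, `L`, `state_a`,
#'   `state_b`; pairs ordered (i < j) by list position.
#' @export
fp_compare_all <- function(fps, allow_raw = FALSE) {
  n <- length(fps)
  if (n < 2) stop("need at least two fingerprints")
  ids <- names(fps)
  if (is.null(ids)) ids <- paste0("fp", seq_len(n))
  Ls <- vapply(fps, function(f) f$L, numeric(1))
  if (length(unique(Ls)) != 1)
    stop("mixed fingerprint lengths: ", paste(unique(Ls), collapse = ", "))
  ok_states <- c("normalized", "adjusted", "population")
  states <- vapply(fps, function(f) f$state, character(1))
  if (!allow_raw && any(!states %in% ok_states))
    stop("comparison of raw fingerprints requires allow_raw = TRUE")

  R <- t(vapply(fps, std_ranks, numeric(4 * Ls[1])))
  C <- tcrossprod(R)
  dimnames(C) <- NULL
  pairs <- which(upper.tri(C), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  data.frame(id_a = ids[pairs[, 1]], id_b = ids[pairs[, 2]],
             rho = pmin(1, pmax(-1, C[pairs])),
             L = unname(Ls[1]), state_a = unname(states[pairs[, 1]]),
             state_b = unname(states[pairs[, 2]]), stringsAsFactors = FALSE)
}

#' Rescale a cross-panel correlation
#'
#' Correlations between fingerprints built on discordant SNP panels are
#' depressed by a roughly constant factor relative to same-panel
#' comparisons (empirically 0.75 for the 23andMe V2-V3 pair); dividing by
#' that factor puts cross-panel correlations on the same-panel scale. The
#' scaling is opt-in: report it alongside, never instead of, the raw rho.
#'
#' @param rho observed cross-panel correlation(s).
#' @param factor positive depression factor; default 0.75.
#' @return `rho / factor`.
#' @export
scale_cross_panel <- function(rho, factor = 0.75) {
  if (length(factor) != 1 || is.na(factor) || factor <= 0)
    stop("scaling factor must be a positive number")
  rho / factor
}

#' Write comparison results to TSV
#' @param cmp data frame from [fp_compare()] or [fp_compare_all()].
#' @param path output path; a `.gz` suffix gzip-compresses.
#' @return `path`, invisibly.
#' @export
write_comparisons <- function(cmp, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines("id_a\tid_b\trho\tL\tstate_a\tstate_b", con)
  writeLines(paste(cmp$id_a, cmp$id_b, sprintf("%.6f", cmp$rho),
                   cmp$L, cmp$state_a, cmp$state_b, sep = "\t"), con)
  invisible(path)
}
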