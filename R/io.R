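# Readers and writers for the package's plain-text dialects: DTC genotype
# files, rsid panels, frequency tables, and serialized fingerprints.

norm_chrom <- function(chrom) {
  chrom <- sub("^chr", "", chrom, ignore.case = TRUE)
  toupper(chrom)
}

#' Read a direct-to-consumer genotype file
#'
#' Parses the tab-separated dialect used by consumer genotyping raw-data
#' downloads: lines starting with `#` are comments; data lines carry
#' rsid, chromosome, position and a 1-2 character genotype string
#' (`"--"` marks a no-call). Identifiers not matching `^rs[0-9]+$`
#' (e.g., internal "i" probes) are skipped and counted, not errors.
#'
#' @param path path to the genotype file.
#' @return A [snp_calls] data frame with an attribute `skip_counts`, a named
#'   integer vector with elements `non_rs` (non-dbSNP identifiers skipped)
#'   and `malformed` (unparseable lines skipped).
#' @export
read_dtc_genotypes <- function(path) {
  lines <- tryCatch(suppressWarnings(readLines(path, warn = FALSE)),
                    error = function(e) stop("cannot read genotype file '",
                                             path, "': ", conditionMessage(e)))
  lines <- sub("\r$", "", lines)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok4 <- lengths(parts) == 4L
  n_malformed <- sum(!ok4)
  parts <- parts[ok4]
  m <- matrix(unlist(parts), ncol = 4L, byrow = TRUE)

  is_rs <- grepl("^rs[0-9]+$", m[, 1])
  n_non_rs <- sum(!is_rs)
  m <- m[is_rs, , drop = FALSE]

  rsid <- as.numeric(sub("^rs", "", m[, 1]))
  pos <- suppressWarnings(as.numeric(m[, 3]))
  gt <- m[, 4]
  gt_ok <- gt == "--" |
    (nchar(gt) >= 1 & nchar(gt) <= 2 &
       grepl(paste0("^[", paste(sub("-", "\\-", ALLELE_SYMBOLS, fixed = TRUE),
                                collapse = ""), "]+$"), gt))
  good <- !is.na(pos) & pos > 0 & gt_ok & rsid > 0
  n_malformed <- n_malformed + sum(!good)
  rsid <- rsid[good]; pos <- pos[good]; gt <- gt[good]
  chrom <- norm_chrom(m[good, 2])

  a1 <- substr(gt, 1, 1)
  a2 <- ifelse(nchar(gt) == 2, substr(gt, 2, 2), NA_character_)
  nocall <- gt == "--"
  a1[nocall] <- NA_character_
  a2[nocall] <- NA_character_

  calls <- snp_calls(rsid, chrom, pos, a1, a2)
  counts <- c(non_rs = n_non_rs, malformed = n_malformed)
  if (sum(counts) > 0)
    warning("skipped ", counts[["non_rs"]], " non-rs identifier(s) and ",
            counts[["malformed"]], " malformed line(s) in '", path, "'")
  attr(calls, "skip_counts") <- counts
  calls
}

#' Write SNP calls in the DTC genotype dialect
#'
#' @param calls a [snp_calls] data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dtc_genotypes <- function(calls, path) {
  gt <- ifelse(is.na(calls$a1) & is.na(calls$a2), "--",
               paste0(ifelse(is.na(calls$a1), "", calls$a1),
                      ifelse(is.na(calls$a2), "", calls$a2)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# rsid\tchromosome\tposition\tgenotype", con)
  writeLines(paste(paste0("rs", format(calls$rsid, scientific = FALSE,
                                       trim = TRUE)),
                   calls$chrom,
                   format(calls$pos, scientific = FALSE, trim = TRUE),
                   gt, sep = "\t"), con)
  invisible(path)
}

#' Read an rsid panel file
#'
#' One identifier per line, either `rsNNN` or a bare integer.
#'
#' @param path path to the panel file.
#' @param name panel tag; defaults to the file stem.
#' @return A [panel] object.
#' @export
read_panel <- function(path, name = NULL) {
  lines <- tryCatch(suppressWarnings(readLines(path, warn = FALSE)),
                    error = function(e) stop("cannot read panel file '",
                                             path, "': ", conditionMessage(e)))
  lines <- trimws(sub("\r$", "", lines))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("panel file '", path, "' contains no rsids")
  ok <- grepl("^(rs)?[0-9]+$", lines)
  if (any(!ok))
    stop("invalid panel entries, e.g. '", lines[which(!ok)[1]], "'")
  rsids <- as.numeric(sub("^rs", "", lines))
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  panel(name, rsids)
}

#' Write an rsid panel file
#' @param pan a [panel] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(pan, path) {
  writeLines(paste0("rs", format(pan$rsids, scientific = FALSE, trim = TRUE)),
             path)
  invisible(path)
}

#' Read a per-rsid allele-frequency table
#'
#' Tab-separated columns `rsid, f_A, f_C, f_G, f_T`; a header line is
#' detected and skipped.
#'
#' @param path path to the TSV file.
#' @return A [frequency_table] data frame.
#' @export
read_frequency_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", comment.char = "#")
  if (ncol(df) != 5)
    stop("frequency table must have 5 columns (rsid, f_A, f_C, f_G, f_T)")
  if (grepl("[^0-9rs]", df[1, 1])) df <- df[-1, , drop = FALSE]  # header row
  frequency_table(as.numeric(sub("^rs", "", df[, 1])),
                  as.numeric(df[, 2]), as.numeric(df[, 3]),
                  as.numeric(df[, 4]), as.numeric(df[, 5]))
}

#' Write a per-rsid allele-frequency table
#' @param ft a [frequency_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(ft, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("rsid\tf_A\tf_C\tf_G\tf_T", con)
  writeLines(paste(format(ft$rsid, scientific = FALSE, trim = TRUE),
                   sprintf("%.12g", ft$f_A), sprintf("%.12g", ft$f_C),
                   sprintf("%.12g", ft$f_G), sprintf("%.12g", ft$f_T),
                   sep = "\t"), con)
  invisible(path)
}

#' Serialize a fingerprint to a text file
#'
#' The on-disk format is header lines `#genofp<TAB>version=1`, `#L=`,
#' `#state=`, `#panel=`, `#n_snps=` (plus `#population=`/`#n_members=` for
#' population fingerprints and `#adjusted_to=` for adjusted ones), followed
#' by four tab-separated rows of L values (rows A, C, G, T) at `%.12g`
#' precision.
#'
#' @param fp a [fingerprint] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fingerprint <- function(fp, path) {
  stopifnot(inherits(fp, "genofp"))
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c("#genofp\tversion=1",
           paste0("#L=", fp$L),
           paste0("#state=", fp$state),
           paste0("#panel=", if (is.na(fp$panel)) "" else fp$panel),
           paste0("#n_snps=", fp$n_snps))
  if (!is.null(fp$id)) hdr <- c(hdr, paste0("#id=", fp$id))
  if (identical(fp$state, "population"))
    hdr <- c(hdr, paste0("#population=", fp$population),
             paste0("#n_members=", fp$n_members))
  if (identical(fp$state, "adjusted") && !is.null(fp$adjusted_to))
    hdr <- c(hdr, paste0("#adjusted_to=", fp$adjusted_to))
  writeLines(hdr, con)
  for (r in 1:4)
    writeLines(paste(sprintf("%.12g", fp$values[r, ]), collapse = "\t"), con)
  invisible(path)
}

#' Read a serialized fingerprint
#'
#' @param path path written by [write_fingerprint()].
#' @return A [fingerprint] object.
#' @export
read_fingerprint <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6 || !startsWith(lines[1], "#genofp"))
    stop("'", path, "' is not a genofp fingerprint file")
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  get <- function(key) {
    hit <- grep(paste0("^#", key, "="), hdr, value = TRUE)
    if (length(hit) == 0) return(NA_character_)
    sub(paste0("^#", key, "="), "", hit[1])
  }
  L <- as.integer(get("L"))
  state <- get("state")
  if (is.na(L) || L < 1) stop("missing or invalid #L header")
  if (!state %in% c("raw", "normalized", "population", "adjusted"))
    stop("invalid #state header: '", state, "'")
  if (length(body) != 4)
    stop("expected 4 data rows, found ", length(body))
  vals <- lapply(strsplit(body, "\t", fixed = TRUE), as.numeric)
  if (any(lengths(vals) != L))
    stop("row length does not match #L=", L)
  values <- do.call(rbind, vals)
  pan <- get("panel")
  id <- get("id")
  fp <- new_fingerprint(values, state = state,
                        panel = if (!nzchar(pan) || is.na(pan)) NA_character_ else pan,
                        n_snps = as.integer(get("n_snps")),
                        id = if (is.na(id)) NULL else id)
  if (state == "population") {
    fp$population <- get("population")
    fp$n_members <- as.integer(get("n_members"))
  }
  if (state == "adjusted") {
    adj <- get("adjusted_to")
    if (!is.na(adj)) fp$adjusted_to <- adj
  }
  fp
}
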