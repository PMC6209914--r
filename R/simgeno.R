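# Synthetic cohort generator: Balding-Nichols differentiated populations,
# Mendelian pedigrees (PO/FS/HS/AV/CO/second-cousin/unrelated pairs),
# overlapping SNP panels emulating successive array designs, no-calls and
# genotyping errors. All randomness flows from the single seed in the
# config; truth tables record population, relationship and panel per
# individual so downstream tests never re-derive them.

RELATIONSHIP_CODES <- c("PO", "FS", "HS", "AV", "CO", "C2", "UN")

#' Simulation configuration
#'
#' @param n_populations number of populations (>= 1).
#' @param fst Balding-Nichols differentiation, a single value in (0, 1) or
#'   one per population.
#' @param n_per_pop unrelated founders simulated per population.
#' @param pedigree character vector of relationship pairs to instantiate,
#'   codes from `PO` (parent-offspring), `FS` (full siblings), `HS` (half
#'   siblings), `AV` (avuncular), `CO` (first cousins), `C2` (second
#'   cousins), `UN` (unrelated); one pair per entry, assigned to
#'   populations round-robin.
#' @param n_snps number of SNPs.
#' @param panel_sizes optional length-2 vector of panel sizes (smaller
#'   "V2"-like first), enabling cross-panel experiments.
#' @param panel_overlap fraction of the first panel shared with the second
#'   (`|A & B| / |A|`).
#' @param panel_names tags for the two panels.
#' @param no_call_rate per-genotype no-call probability in `[0, 1)`.
#' @param error_rate per-allele symmetric flip probability in `[0, 1)`.
#' @param seed mandatory integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_populations = 1, fst = 0.1, n_per_pop = 0,
                       pedigree = character(), n_snps = 1000,
                       panel_sizes = NULL, panel_overlap = NULL,
                       panel_names = c("V2", "V3"),
                       no_call_rate = 0, error_rate = 0, seed) {
  if (missing(seed) || is.na(seed)) stop("seed is mandatory")
  if (n_populations < 1) stop("need at least one population")
  fst <- rep_len(fst, n_populations)
  if (any(fst <= 0 | fst >= 1)) stop("fst must lie in (0, 1)")
  if (no_call_rate < 0 || no_call_rate >= 1 ||
      error_rate < 0 || error_rate >= 1)
    stop("rates must lie in [0, 1)")
  if (length(pedigree) > 0 && any(!pedigree %in% RELATIONSHIP_CODES))
    stop("unknown relationship code(s): ",
         paste(setdiff(pedigree, RELATIONSHIP_CODES), collapse = ", "))
  if (n_per_pop == 0 && length(pedigree) == 0)
    stop("empty cohort: set n_per_pop and/or pedigree")
  if (!is.null(panel_sizes)) {
    stopifnot(length(panel_sizes) == 2, all(panel_sizes >= 1))
    if (is.null(panel_overlap) || panel_overlap < 0 || panel_overlap > 1)
      stop("panel_overlap must lie in [0, 1]")
  }
  structure(list(n_populations = as.integer(n_populations), fst = fst,
                 n_per_pop = as.integer(n_per_pop), pedigree = pedigree,
                 n_snps = as.integer(n_snps), panel_sizes = panel_sizes,
                 panel_overlap = panel_overlap, panel_names = panel_names,
                 no_call_rate = no_call_rate, error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

with_preserved_rng <- function(expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  expr
}

# Hardy-Weinberg founder and Mendelian-transmission child, as alt-allele
# dosage vectors
sim_founder <- function(q) stats::rbinom(length(q), 2, q)
sim_child <- function(ga, gb)
  stats::rbinom(length(ga), 1, ga / 2) + stats::rbinom(length(gb), 1, gb / 2)

# generate the focal pair for one relationship, given population freqs q
sim_rel_pair <- function(code, q) {
  f <- function() sim_founder(q)
  switch(code,
    PO = { p1 <- f(); list(a = p1, b = sim_child(p1, f())) },
    FS = { p1 <- f(); p2 <- f()
           list(a = sim_child(p1, p2), b = sim_child(p1, p2)) },
    HS = { shared <- f()
           list(a = sim_child(shared, f()), b = sim_child(shared, f())) },
    AV = { g1 <- f(); g2 <- f()
           s1 <- sim_child(g1, g2); s2 <- sim_child(g1, g2)
           list(a = s1, b = sim_child(s2, f())) },
    CO = { g1 <- f(); g2 <- f()
           s1 <- sim_child(g1, g2); s2 <- sim_child(g1, g2)
           list(a = sim_child(s1, f()), b = sim_child(s2, f())) },
    C2 = { g1 <- f(); g2 <- f()
           s1 <- sim_child(g1, g2); s2 <- sim_child(g1, g2)
           c1 <- sim_child(s1, f()); c2 <- sim_child(s2, f())
           list(a = sim_child(c1, f()), b = sim_child(c2, f())) },
    UN = list(a = f(), b = f()),
    stop("unknown relationship code '", code, "'"))
}

#' Simulate a genotyped cohort
#'
#' Ancestral allele frequencies are drawn uniformly on (0.05, 0.95); each
#' population's frequencies follow the Balding-Nichols Beta distribution
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` around the ancestral frequency p.
#' Founders are Hardy-Weinberg draws from their population's frequencies;
#' pedigree individuals arise by Mendelian transmission. rsid numbers are
#' distinct random integers in 1..2e8, independent of genomic position, so
#' the mod-L column hash distributes as in real data. Symmetric per-allele
#' genotyping errors and per-genotype no-calls are applied at the
#' configured rates. Fully reproducible from the config seed (the caller's
#' RNG state is preserved).
#'
#' @param cfg a [sim_config].
#' @return A list of class `sim_cohort`: `snps` (data frame rsid, chrom,
#'   pos, ref, alt, p_anc), `p_pop` (SNPs x populations alt-allele
#'   frequency matrix), `dosage` (individuals x SNPs alt-allele counts,
#'   `NA` = no-call), `individuals` (id, population, kind, panel),
#'   `relationships` (id_a, id_b, relationship), `panels` (list of two
#'   [panel] objects or `NULL`), `config`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_preserved_rng({
    set.seed(cfg$seed)
    m <- cfg$n_snps
    K <- cfg$n_populations
    pop_names <- paste0("pop", seq_len(K))

    # SNP map: blocks of autosomes, increasing positions, random rsids
    chrom <- sort(rep_len(1:22, m))
    pos <- stats::ave(rep(1, m), chrom, FUN = cumsum) * 1000
    rsid <- sample(2e8, m)
    ref_i <- sample.int(4, m, replace = TRUE)
    alt_i <- 1L + (ref_i - 1L + sample.int(3, m, replace = TRUE)) %% 4L
    p_anc <- stats::runif(m, 0.05, 0.95)

    p_pop <- vapply(seq_len(K), function(k) {
      F <- cfg$fst[k]
      stats::rbeta(m, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
    }, numeric(m))
    colnames(p_pop) <- pop_names

    dosage <- list(); ind <- list(); rel <- list()
    for (k in seq_len(K)) {
      for (i in seq_len(cfg$n_per_pop)) {
        id <- sprintf("%s_F%03d", pop_names[k], i)
        dosage[[id]] <- sim_founder(p_pop[, k])
        ind[[id]] <- data.frame(id = id, population = pop_names[k],
                                kind = "founder", stringsAsFactors = FALSE)
      }
    }
    for (j in seq_along(cfg$pedigree)) {
      code <- cfg$pedigree[j]
      k <- (j - 1L) %% K + 1L
      pr <- sim_rel_pair(code, p_pop[, k])
      ida <- sprintf("%s%02d_a", code, j)
      idb <- sprintf("%s%02d_b", code, j)
      dosage[[ida]] <- pr$a
      dosage[[idb]] <- pr$b
      for (id in c(ida, idb))
        ind[[id]] <- data.frame(id = id, population = pop_names[k],
                                kind = "pair", stringsAsFactors = FALSE)
      rel[[j]] <- data.frame(id_a = ida, id_b = idb, relationship = code,
                             stringsAsFactors = FALSE)
    }
    dosage <- do.call(rbind, dosage)
    individuals <- do.call(rbind, ind)
    rownames(individuals) <- NULL
    relationships <- if (length(rel)) do.call(rbind, rel) else
      data.frame(id_a = character(0), id_b = character(0),
                 relationship = character(0))

    # per-allele symmetric flip errors, then per-genotype no-calls
    if (cfg$error_rate > 0) {
      g <- as.vector(dosage)
      flips_alt <- stats::rbinom(length(g), g, cfg$error_rate)
      flips_ref <- stats::rbinom(length(g), 2 - g, cfg$error_rate)
      dosage[] <- g - flips_alt + flips_ref
    }
    if (cfg$no_call_rate > 0)
      dosage[stats::runif(length(dosage)) < cfg$no_call_rate] <- NA

    panels <- NULL
    if (!is.null(cfg$panel_sizes)) {
      panels <- make_panels(rsid, sizes = cfg$panel_sizes,
                            overlap = cfg$panel_overlap,
                            names = cfg$panel_names)
      individuals$panel <- cfg$panel_names[1L +
        (seq_len(nrow(individuals)) - 1L) %% 2L]
    } else {
      individuals$panel <- NA_character_
    }

    structure(list(
      snps = data.frame(rsid = rsid, chrom = chrom, pos = pos,
                        ref = NUCS[ref_i], alt = NUCS[alt_i],
                        p_anc = p_anc, stringsAsFactors = FALSE),
      p_pop = p_pop, dosage = dosage, individuals = individuals,
      relationships = relationships, panels = panels, config = cfg),
      class = "sim_cohort")
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("simulated cohort:", nrow(x$dosage), "individuals,",
      nrow(x$snps), "SNPs,", ncol(x$p_pop), "population(s),",
      nrow(x$relationships), "relationship pair(s)\n")
  invisible(x)
}

#' Draw two overlapping rsid panels
#'
#' Emulates successive versions of an array design: two rsid subsets with a
#' configured overlap fraction `|A & B| / |A|` of the first (smaller)
#' panel.
#'
#' @param rsids pool of rsid numbers to draw from.
#' @param sizes length-2 vector of panel sizes.
#' @param overlap overlap fraction in `[0, 1]`.
#' @param names panel tags.
#' @param seed optional seed (caller RNG preserved if given).
#' @return List of two [panel] objects.
#' @export
make_panels <- function(rsids, sizes, overlap, names = c("V2", "V3"),
                        seed = NULL) {
  stopifnot(length(sizes) == 2)
  if (overlap < 0 || overlap > 1) stop("overlap must lie in [0, 1]")
  n_ov <- round(overlap * sizes[1])
  if (n_ov > min(sizes))
    stop("overlap of ", n_ov, " rsids impossible with panel sizes ",
         sizes[1], " and ", sizes[2])
  if (sizes[1] + sizes[2] - n_ov > length(rsids))
    stop("panels need ", sizes[1] + sizes[2] - n_ov,
         " distinct rsids but only ", length(rsids), " are available")
  draw <- function() {
    pool <- sample(rsids, sizes[1] + sizes[2] - n_ov)
    shared <- pool[seq_len(n_ov)]
    only_a <- pool[seq_len(sizes[1] - n_ov) + n_ov]
    only_b <- pool[seq_len(sizes[2] - n_ov) + sizes[1]]
    list(panel(names[1], c(shared, only_a)),
         panel(names[2], c(shared, only_b)))
  }
  if (!is.null(seed)) with_preserved_rng({ set.seed(seed); draw() })
  else draw()
}

#' SNP calls for one simulated individual
#'
#' Converts a dosage row into the [snp_calls] representation (alt-allele
#' count 0/1/2 mapped through ref/alt symbols; `NA` dosage becomes a
#' no-call), optionally restricted to a panel.
#'
#' @param cohort a `sim_cohort`.
#' @param id individual identifier.
#' @param pan optional [panel] object or panel name from the cohort.
#' @return A [snp_calls] data frame.
#' @export
calls_for <- function(cohort, id, pan = NULL) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (!id %in% rownames(cohort$dosage))
    stop("unknown individual '", id, "'")
  if (is.character(pan) && length(pan) == 1 && !inherits(pan, "panel")) {
    hit <- which(vapply(cohort$panels, function(p) p$name == pan, logical(1)))
    if (length(hit) != 1) stop("unknown panel '", pan, "'")
    pan <- cohort$panels[[hit]]
  }
  g <- cohort$dosage[id, ]
  s <- cohort$snps
  keep <- if (is.null(pan)) rep(TRUE, length(g)) else s$rsid %in% pan$rsids
  g <- g[keep]; s <- s[keep, , drop = FALSE]
  a1 <- ifelse(is.na(g), NA_character_, ifelse(g >= 1, s$alt, s$ref))
  a2 <- ifelse(is.na(g), NA_character_, ifelse(g == 2, s$alt, s$ref))
  snp_calls(s$rsid, as.character(s$chrom), s$pos, a1, a2)
}

#' True allele-frequency table for a simulated population
#'
#' Builds a [frequency_table] from the simulator's per-population
#' alt-allele frequencies, mapped onto nucleotide rows through each SNP's
#' ref/alt symbols. Usable directly with [raw_fingerprint_freq()].
#'
#' @param cohort a `sim_cohort`.
#' @param population population name (e.g., `"pop1"`).
#' @return A [frequency_table].
#' @export
freq_table_for <- function(cohort, population) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (!population %in% colnames(cohort$p_pop))
    stop("unknown population '", population, "'")
  q <- cohort$p_pop[, population]
  s <- cohort$snps
  f <- matrix(0, nrow(s), 4, dimnames = list(NULL, NUCS))
  f[cbind(seq_len(nrow(s)), match(s$alt, NUCS))] <- q
  f[cbind(seq_len(nrow(s)), match(s$ref, NUCS))] <- 1 - q
  frequency_table(s$rsid, f[, "A"], f[, "C"], f[, "G"], f[, "T"])
}

#' Convert a simulated cohort to a minor-allele genotype matrix
#'
#' Folds alt-allele dosages to minor-allele counts (per SNP, relative to
#' the cohort-wide allele frequency) and returns a [geno_matrix] suitable
#' for [maf_ld_prune()] and [fp_pca()].
#'
#' @param cohort a `sim_cohort`.
#' @param ids individuals to include (default all).
#' @return A [geno_matrix].
#' @export
as_geno_matrix <- function(cohort, ids = NULL) {
  stopifnot(inherits(cohort, "sim_cohort"))
  d <- cohort$dosage
  if (!is.null(ids)) d <- d[ids, , drop = FALSE]
  flip <- colMeans(d, na.rm = TRUE) / 2 > 0.5
  d[, flip] <- 2 - d[, flip]
  geno_matrix(d, cohort$snps$rsid, cohort$snps$chrom, cohort$snps$pos)
}

#' Write a simulated cohort to disk
#'
#' Emits one DTC-dialect genotype file per individual (restricted to the
#' individual's assigned panel when panels are configured), panel files,
#' one true frequency table per population, and truth TSVs
#' (`individuals.tsv`, `relationships.tsv`).
#'
#' @param cohort a `sim_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(file.path(dir, "genotypes"), recursive = TRUE,
             showWarnings = FALSE)
  for (i in seq_len(nrow(cohort$individuals))) {
    id <- cohort$individuals$id[i]
    pan <- cohort$individuals$panel[i]
    calls <- calls_for(cohort, id, if (is.na(pan)) NULL else pan)
    write_dtc_genotypes(calls, file.path(dir, "genotypes",
                                         paste0(id, ".txt")))
  }
  if (!is.null(cohort$panels))
    for (p in cohort$panels)
      write_panel(p, file.path(dir, paste0("panel_", p$name, ".txt")))
  for (pop in colnames(cohort$p_pop))
    write_frequency_table(freq_table_for(cohort, pop),
                          file.path(dir, paste0("freqs_", pop, ".tsv")))
  utils::write.table(cohort$individuals, file.path(dir, "individuals.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$relationships,
                     file.path(dir, "relationships.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
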