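# Shared fixtures. The two simulated study cohorts are expensive enough to
# build that they are computed lazily, once per test run, and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# a synthetic raw fingerprint: column-centered noise (every column sums to 0,
# as for genuine raw fingerprints)
rand_raw_fp <- function(L, seed = 1, id = NULL) {
  set.seed(seed)
  v <- matrix(rnorm(4 * L), 4, L)
  v <- sweep(v, 2, colMeans(v))
  new_fingerprint(v, "raw", id = id)
}

rand_norm_fp <- function(L, seed = 1, id = NULL)
  normalize_fingerprint(rand_raw_fp(L, seed, id))

# quick snp_calls builder: homozygous/heterozygous genotypes on chromosome 1
mk_calls <- function(rsid, gt, chrom = "1") {
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 2, 2)
  snp_calls(rsid, rep_len(chrom, length(rsid)), seq_along(rsid) * 100,
            ifelse(a1 == "", NA, a1), ifelse(a2 == "", NA, a2))
}

# cohort-mode normalized fingerprints for a set of simulated individuals
sim_norm_fps <- function(cohort, ids, L, pan = NULL) {
  calls <- lapply(stats::setNames(ids, ids), function(i)
    filter_calls(calls_for(cohort, i, pan)))
  raw <- raw_fingerprints_cohort(calls, L = L,
                                 panel_name = if (is.null(pan)) NA_character_
                                              else pan)
  lapply(raw$fingerprints, normalize_fingerprint)
}

# Study cohort 1: population structure. Three populations differentiated at
# F_ST = 0.1, 50 unrelated individuals each, 100,000 SNPs, no noise. The
# SNP count is a scaled-down array panel chosen to preserve the regime the
# method operates in: many SNPs per fingerprint column even at the largest
# L studied (100000 / 5000 = 20 per column).
structure_cohort <- function() cached("structure_cohort", {
  simulate_cohort(sim_config(n_populations = 3, fst = 0.1, n_per_pop = 50,
                             n_snps = 100000, seed = 20260901))
})

structure_fps <- function(L) cached(paste0("structure_fps_", L), {
  co <- structure_cohort()
  sim_norm_fps(co, co$individuals$id, L)
})

structure_labels <- function() {
  co <- structure_cohort()
  stats::setNames(co$individuals$population, co$individuals$id)
}

# Study cohort 2: pedigree / cross-panel. One population, 30 unrelated
# founders plus 10 pairs per relationship class, 15,000 SNPs, and two
# overlapping panels emulating successive array designs (9,000 and 14,000
# rsids, 95% of the smaller panel shared).
pedigree_cohort <- function() cached("pedigree_cohort", {
  simulate_cohort(sim_config(
    n_populations = 1, fst = 0.05, n_per_pop = 30,
    pedigree = rep(c("PO", "FS", "HS", "AV", "CO", "UN"), each = 10),
    n_snps = 15000, panel_sizes = c(9000, 14000), panel_overlap = 0.95,
    seed = 20260902))
})

# Relationship-analysis summary on the pedigree cohort at L = 5000:
# same-panel and cross-panel rho per relationship pair, self cross-panel
# rho per individual, population-adjusted rho and KING kinship per pair.
pedigree_analysis <- function() cached("pedigree_analysis", {
  co <- pedigree_cohort()
  L <- 5000
  ids <- co$individuals$id
  fpA <- sim_norm_fps(co, ids, L, co$panels[[1]])   # V2-like
  fpB <- sim_norm_fps(co, ids, L, co$panels[[2]])   # V3-like

  rel <- co$relationships
  rho_same <- vapply(seq_len(nrow(rel)), function(j)
    fp_compare(fpB[[rel$id_a[j]]], fpB[[rel$id_b[j]]])$rho, numeric(1))
  rho_cross <- vapply(seq_len(nrow(rel)), function(j)
    fp_compare(fpA[[rel$id_a[j]]], fpB[[rel$id_b[j]]])$rho, numeric(1))
  rho_self_cross <- vapply(ids, function(i)
    fp_compare(fpA[[i]], fpB[[i]])$rho, numeric(1))

  founders <- co$individuals$id[co$individuals$kind == "founder"]
  popfp <- population_fingerprint(fpB[founders], "pop1")
  adj <- lapply(fpB, adjust_fingerprint, pop = popfp)
  rho_adj <- vapply(seq_len(nrow(rel)), function(j)
    fp_compare(adj[[rel$id_a[j]]], adj[[rel$id_b[j]]])$rho, numeric(1))
  phi <- vapply(seq_len(nrow(rel)), function(j)
    king_robust(co$dosage[rel$id_a[j], ], co$dosage[rel$id_b[j], ])$phi,
    numeric(1))

  list(cohort = co, rel = rel, rho_same = rho_same, rho_cross = rho_cross,
       rho_self_cross = rho_self_cross, rho_adj = rho_adj, phi = phi,
       adj = adj, founders = founders, fpB = fpB)
})

class_means <- function(x, class) tapply(x, class, mean)
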