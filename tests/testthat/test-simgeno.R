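test_that("configuration validation rejects impossible study designs", {
  expect_error(sim_config(n_per_pop = 5), "seed")
  expect_error(sim_config(n_per_pop = 5, fst = 1.2, seed = 1), "\\(0, 1\\)")
  expect_error(sim_config(n_per_pop = 5, no_call_rate = 1, seed = 1),
               "rates")
  expect_error(sim_config(n_per_pop = 5, pedigree = "XX", seed = 1),
               "relationship code")
  expect_error(sim_config(seed = 1), "empty cohort")
})

test_that("offspring genotypes obey Mendelian transmission without noise", {
  co <- simulate_cohort(sim_config(pedigree = rep("PO", 5), n_snps = 3000,
                                   seed = 7))
  rel <- co$relationships
  for (j in seq_len(nrow(rel))) {
    parent <- co$dosage[rel$id_a[j], ]
    child <- co$dosage[rel$id_b[j], ]
    # a homozygous parent always transmits that allele
    expect_equal(sum(parent == 0 & child == 2), 0)
    expect_equal(sum(parent == 2 & child == 0), 0)
  }
})

test_that("population frequencies collapse to ancestral as F_ST vanishes", {
  co <- simulate_cohort(sim_config(n_populations = 2, fst = 1e-4,
                                   n_per_pop = 2, n_snps = 2000, seed = 8))
  expect_lt(max(abs(co$p_pop - co$snps$p_anc)), 0.05)
  expect_lt(mean((co$p_pop[, 1] - co$snps$p_anc)^2), 1e-3)
})

test_that("realized differentiation matches the Hudson F_ST estimator", {
  co <- simulate_cohort(sim_config(n_populations = 2, fst = 0.1,
                                   n_per_pop = 50, n_snps = 10000,
                                   seed = 99))
  ids1 <- co$individuals$id[co$individuals$population == "pop1"]
  ids2 <- co$individuals$id[co$individuals$population == "pop2"]
  p1 <- colMeans(co$dosage[ids1, ]) / 2
  p2 <- colMeans(co$dosage[ids2, ]) / 2
  n1 <- 2 * length(ids1); n2 <- 2 * length(ids2)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  fst_hat <- mean(num) / mean(den)
  expect_equal(fst_hat, 0.1, tolerance = 0.02)
})

test_that("panels reach the configured sizes and overlap", {
  rsids <- 1:5000
  eq <- make_panels(rsids, sizes = c(100, 100), overlap = 1, seed = 1)
  expect_setequal(eq[[1]]$rsids, eq[[2]]$rsids)
  dis <- make_panels(rsids, sizes = c(100, 150), overlap = 0, seed = 1)
  expect_equal(length(intersect(dis[[1]]$rsids, dis[[2]]$rsids)), 0)
  p <- make_panels(rsids, sizes = c(550, 900), overlap = 0.9, seed = 1)
  expect_equal(length(intersect(p[[1]]$rsids, p[[2]]$rsids)), 495)
  expect_equal(length(p[[1]]$rsids), 550)
  expect_equal(length(p[[2]]$rsids), 900)
  expect_error(make_panels(1:100, sizes = c(90, 90), overlap = 0),
               "distinct rsids")
  expect_error(make_panels(rsids, sizes = c(100, 50), overlap = 1),
               "impossible")
})

test_that("simulation is reproducible from its seed and preserves caller RNG", {
  cfg <- sim_config(n_populations = 2, fst = 0.05, n_per_pop = 3,
                    pedigree = c("FS", "UN"), n_snps = 500,
                    no_call_rate = 0.02, error_rate = 0.01, seed = 12)
  set.seed(5000)
  before <- runif(1)
  set.seed(5000)
  co1 <- simulate_cohort(cfg)
  after <- runif(1)
  expect_equal(after, before)              # caller RNG untouched
  co2 <- simulate_cohort(cfg)
  expect_identical(co1$dosage, co2$dosage)
  expect_identical(co1$snps$rsid, co2$snps$rsid)
})

test_that("noise rates are realized approximately", {
  co <- simulate_cohort(sim_config(n_per_pop = 10, n_snps = 5000,
                                   no_call_rate = 0.05, seed = 21))
  expect_lt(abs(mean(is.na(co$dosage)) - 0.05), 0.01)

  # allele-flip errors break strict Mendelian consistency
  co_err <- simulate_cohort(sim_config(pedigree = rep("PO", 5),
                                       n_snps = 5000, error_rate = 0.02,
                                       seed = 22))
  rel <- co_err$relationships
  viol <- sum(vapply(seq_len(nrow(rel)), function(j) {
    p <- co_err$dosage[rel$id_a[j], ]; c <- co_err$dosage[rel$id_b[j], ]
    sum(p == 0 & c == 2) + sum(p == 2 & c == 0)
  }, numeric(1)))
  expect_gt(viol, 0)
})

test_that("truth tables cover every individual and instantiated pair", {
  co <- pedigree_cohort()
  expect_setequal(co$individuals$id, rownames(co$dosage))
  expect_true(all(co$relationships$id_a %in% co$individuals$id))
  expect_true(all(co$relationships$id_b %in% co$individuals$id))
  expect_equal(nrow(co$relationships), 60)
  expect_true(all(table(co$relationships$relationship) == 10))
})

test_that("cohorts round-trip through the on-disk layout", {
  co <- simulate_cohort(sim_config(n_populations = 1, fst = 0.05,
                                   n_per_pop = 3, n_snps = 200,
                                   panel_sizes = c(80, 120),
                                   panel_overlap = 0.75, seed = 33))
  dir <- withr::local_tempdir()
  write_sim_cohort(co, dir)
  id <- co$individuals$id[1]
  back <- read_dtc_genotypes(file.path(dir, "genotypes",
                                       paste0(id, ".txt")))
  pan_name <- co$individuals$panel[1]
  pan <- read_panel(file.path(dir, paste0("panel_", pan_name, ".txt")))
  expect_setequal(back$rsid, intersect(co$snps$rsid, pan$rsids))
  ft <- read_frequency_table(file.path(dir, "freqs_pop1.tsv"))
  expect_equal(nrow(ft), 200)
  truth <- utils::read.table(file.path(dir, "individuals.tsv"),
                             header = TRUE, sep = "\t")
  expect_setequal(truth$id, co$individuals$id)
})

test_that("cross-panel depression is a roughly constant ratio across classes", {
  pa <- pedigree_analysis()
  cls <- pa$rel$relationship
  informative <- c("PO", "FS", "HS", "AV", "CO")
  ratio <- class_means(pa$rho_cross, cls)[informative] /
    class_means(pa$rho_same, cls)[informative]
  expect_lt(stats::sd(ratio) / mean(ratio), 0.15)
  # and same-individual cross-panel comparisons dominate every relative pair
  expect_gt(min(pa$rho_self_cross),
            max(pa$rho_same[cls != "UN"], pa$rho_cross[cls != "UN"]))
})
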