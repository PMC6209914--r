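test_that("column hash is rsid modulo L", {
  expect_equal(column_of(1801133, 1000), 133)
  # long division: 1801133 = 360 * 5000 + 1133
  expect_equal(column_of(1801133, 5000), 1133)
  expect_equal(column_of(7, 1), 0)
  expect_equal(column_of(c(10, 11, 12), 10), c(0, 1, 2))
  expect_error(column_of(5, 0), "positive")
})

test_that("filter_calls keeps only complete autosomal ACGT biallelic calls", {
  calls <- snp_calls(
    rsid = c(1801133, 2, 3, 4, 5, 6),
    chrom = c("1", "X", "22", "1", "MT", "2"),
    pos = 1:6 * 10,
    a1 = c("A", "A", "I", "C", "G", "T"),
    a2 = c("G", "A", "D", NA, "G", "T"))
  out <- filter_calls(calls)
  expect_equal(out$rsid, c(1801133, 6))
  counts <- attr(out, "filter_counts")
  expect_equal(unname(counts["non_autosomal"]), 2)  # X and MT
  expect_equal(unname(counts["non_acgt"]), 1)       # {I,D}
  expect_equal(unname(counts["incomplete"]), 1)     # half-call

  pan <- panel("p", 6)
  out2 <- filter_calls(calls, pan)
  expect_equal(out2$rsid, 6)
  expect_equal(unname(attr(out2, "filter_counts")["not_in_panel"]), 1)
})

test_that("per-SNP-frequency raw fingerprints tally n_X - 2 f_X", {
  ft <- frequency_table(42, 0.5, 0.5, 0, 0)
  fp <- raw_fingerprint_freq(mk_calls(42, "AA"), L = 10, freqs = ft)
  expect_equal(fp$values[, 42 %% 10 + 1], c(A = 1, C = -1, G = 0, T = 0))
  expect_equal(sum(abs(fp$values[, -(42 %% 10 + 1)])), 0)
  expect_equal(fp$n_snps, 1L)
  expect_equal(fp$state, "raw")

  # observation equal to expectation: zero fingerprint
  fp0 <- raw_fingerprint_freq(mk_calls(42, "AC"), L = 10, freqs = ft)
  expect_equal(max(abs(fp0$values)), 0)
})

test_that("raw fingerprint columns always sum to zero", {
  co <- simulate_cohort(sim_config(n_per_pop = 1, pedigree = "UN",
                                   n_snps = 2000, seed = 11))
  ft <- freq_table_for(co, "pop1")
  calls <- filter_calls(calls_for(co, co$individuals$id[1]))
  fp <- raw_fingerprint_freq(calls, L = 100, freqs = ft)
  expect_lt(max(abs(colSums(fp$values))), 1e-9)
})

test_that("frequency lookups warn on missing rsids and reject bad tables", {
  ft <- frequency_table(1, 1, 0, 0, 0)
  calls <- mk_calls(c(1, 2), c("AA", "CC"))
  expect_warning(fp <- raw_fingerprint_freq(calls, L = 5, freqs = ft),
                 "absent")
  expect_equal(fp$n_snps, 1L)
  expect_warning(raw_fingerprint_freq(mk_calls(c(3, 3), c("AA", "AA")),
                                      L = 5, freqs = frequency_table(
                                        3, 1, 0, 0, 0)),
                 "duplicate")
})

test_that("cohort-mode fingerprints subtract pooled column expectations", {
  # identical individuals: everyone equals the cohort mean
  calls <- mk_calls(c(10, 21, 32), c("AA", "CG", "TT"))
  res <- raw_fingerprints_cohort(list(i1 = calls, i2 = calls), L = 10)
  expect_equal(max(abs(res$fingerprints$i1$values)), 0)
  expect_equal(max(abs(res$fingerprints$i2$values)), 0)

  # opposite homozygotes at one SNP: +/-1 around the pooled frequency 0.5
  res2 <- raw_fingerprints_cohort(
    list(a = mk_calls(7, "AA"), b = mk_calls(7, "GG")), L = 5)
  expect_equal(res2$fingerprints$a$values[, 7 %% 5 + 1],
               c(A = 1, C = 0, G = -1, T = 0))
  expect_equal(res2$fingerprints$b$values[, 7 %% 5 + 1],
               c(A = -1, C = 0, G = 1, T = 0))

  expect_error(raw_fingerprints_cohort(list(a = calls), L = 10),
               "at least 2")
})

test_that("cohort fingerprints sum to zero under identical coverage", {
  co <- simulate_cohort(sim_config(n_per_pop = 5, n_snps = 1000, seed = 3))
  calls <- lapply(stats::setNames(co$individuals$id, co$individuals$id),
                  function(i) filter_calls(calls_for(co, i)))
  res <- raw_fingerprints_cohort(calls, L = 50)
  total <- Reduce(`+`, lapply(res$fingerprints, function(f) f$values))
  expect_lt(max(abs(total)), 1e-9)
  # column with no SNPs anywhere stays zero for everyone
  expect_true(all(vapply(res$fingerprints, function(f)
    all(is.finite(f$values)), logical(1))))
})

test_that("freq mode with pooled per-rsid frequencies equals cohort mode", {
  co <- simulate_cohort(sim_config(n_per_pop = 6, n_snps = 800, seed = 9))
  ids <- co$individuals$id
  calls <- lapply(stats::setNames(ids, ids),
                  function(i) filter_calls(calls_for(co, i)))
  res <- raw_fingerprints_cohort(calls, L = 40)

  # pooled per-rsid nucleotide frequencies computed independently
  all_calls <- do.call(rbind, calls)
  cnt <- rowsum(
    vapply(c("A", "C", "G", "T"),
           function(x) (all_calls$a1 == x) + (all_calls$a2 == x),
           numeric(nrow(all_calls))),
    group = all_calls$rsid)
  freqs <- cnt / rowSums(cnt)
  ft <- frequency_table(as.numeric(rownames(cnt)), freqs[, "A"],
                        freqs[, "C"], freqs[, "G"], freqs[, "T"])
  for (i in ids[1:3]) {
    fp <- raw_fingerprint_freq(calls[[i]], L = 40, freqs = ft)
    expect_equal(fp$values, res$fingerprints[[i]]$values, tolerance = 1e-9)
  }
})

test_that("normalization matches an explicit two-pass oracle and z-scores rows", {
  # independent elementwise two-pass computation on a 4x3 instance
  v <- matrix(c(2, -1, 0, -1,
                0.5, 0.5, -1, 0,
                3, -3, 1, -1), 4, 3)
  oracle <- v
  for (j in 1:3) {
    x <- oracle[, j]
    x <- x - mean(x)
    s <- sqrt(mean(x^2))
    if (s > 0) x <- x / s
    oracle[, j] <- x
  }
  for (i in 1:4) {
    x <- oracle[i, ]
    x <- x - mean(x)
    s <- sqrt(mean(x^2))
    if (s > 0) x <- x / s
    oracle[i, ] <- x
  }
  fp <- normalize_fingerprint(new_fingerprint(v, "raw"))
  expect_equal(unname(fp$values), oracle, tolerance = 1e-12)

  nf <- rand_norm_fp(1000, seed = 2)
  expect_lt(max(abs(rowMeans(nf$values))), 1e-9)
  expect_lt(max(abs(sqrt(rowMeans(nf$values^2)) - 1)), 1e-9)
})

test_that("degenerate all-zero fingerprints normalize to zero", {
  fp <- normalize_fingerprint(new_fingerprint(matrix(0, 4, 8), "raw"))
  expect_equal(max(abs(fp$values)), 0)
})

test_that("normalization is nearly stable under re-application", {
  # the second column pass re-centers 4-entry columns whose means are
  # O(1/sqrt(L)), so exact idempotence does not hold; rank structure and
  # elementwise values must be nearly unchanged, improving with L
  devs <- vapply(c(500, 5000), function(L) {
    n1 <- rand_norm_fp(L, seed = 5)
    n2 <- normalize_fingerprint(new_fingerprint(n1$values, "raw"))
    expect_gt(fp_compare(n1, new_fingerprint(n2$values, "normalized"))$rho,
              0.999)
    max(abs(n2$values - n1$values))
  }, numeric(1))
  expect_lt(devs[2], devs[1])
  expect_lt(devs[2], 0.05)
})

test_that("congruent rsids hash to one column: genotype swaps are invisible", {
  # rs1013 and rs2013 both land in column 13 at L = 1000; with equal
  # frequencies, exchanging their genotypes cannot change the fingerprint
  ft <- frequency_table(c(1013, 2013, 500), c(0.3, 0.3, 0.5),
                        c(0.7, 0.7, 0.5), c(0, 0, 0), c(0, 0, 0))
  f1 <- raw_fingerprint_freq(mk_calls(c(1013, 2013, 500), c("AA", "AC", "CC")),
                             L = 1000, freqs = ft)
  f2 <- raw_fingerprint_freq(mk_calls(c(1013, 2013, 500), c("AC", "AA", "CC")),
                             L = 1000, freqs = ft)
  expect_identical(f1$values, f2$values)
})

test_that("changing L redistributes but conserves row totals", {
  co <- simulate_cohort(sim_config(n_per_pop = 1, pedigree = "UN",
                                   n_snps = 1500, seed = 13))
  ft <- freq_table_for(co, "pop1")
  calls <- filter_calls(calls_for(co, co$individuals$id[1]))
  f1 <- raw_fingerprint_freq(calls, L = 100, freqs = ft)
  f2 <- raw_fingerprint_freq(calls, L = 200, freqs = ft)
  expect_equal(rowSums(f1$values), rowSums(f2$values), tolerance = 1e-9)
})
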