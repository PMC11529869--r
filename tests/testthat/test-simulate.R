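# Mosaic-chromosome simulator: founders, mosaics, traits, datasets.

test_that("population frequencies degenerate correctly at FST = 0 and one founder", {
  spec0 <- simulation_spec(n_founders = 10, n_samples = 5, m_markers = 200,
                           fst = 0, n_causal = 2, seed = 1)
  f0 <- make_founders(spec0)
  expect_identical(f0$pop_freq[, 1], f0$pop_freq[, 2])
  expect_true(all(f0$p_anc >= 0.05 & f0$p_anc <= 0.5))

  spec1 <- simulation_spec(n_founders = 1, n_samples = 6, m_markers = 100,
                           n_populations = 1, n_causal = 1, seed = 2)
  ds1 <- simulate_dataset(spec1)
  expect_equal(nrow(ds1$founders$dosages), 1L)
  for (i in 1:6) {
    expect_identical(ds1$mosaic$dosages[i, ], ds1$founders$dosages[1, ])
  }
  expect_error(simulation_spec(fst = 1), "fst")
  expect_error(simulation_spec(ancestors_per_related = 200, n_founders = 100,
                               related_fraction = 0.5),
               "exceed")
})

test_that("two-population founders reproduce the target Hudson FST", {
  spec <- simulation_spec(n_founders = 100, n_samples = 5, m_markers = 10000,
                          fst = 0.05, n_causal = 2, seed = 33)
  f <- make_founders(spec)
  g1 <- f$dosages[f$population == 1, ]
  g2 <- f$dosages[f$population == 2, ]
  est <- hudson_fst(colMeans(g1) / 2, colMeans(g2) / 2,
                    2 * nrow(g1), 2 * nrow(g2))
  expect_lt(abs(est - 0.05), 0.02)
})

test_that("mosaic segments replay exactly from the ledger", {
  spec <- simulation_spec(n_founders = 20, n_samples = 20, m_markers = 6000,
                          segment_len = 2000, n_causal = 5, seed = 7)
  f <- make_founders(spec)
  mo <- mosaic_individuals(f, spec)
  expect_equal(mo$segment_starts, c(1L, 2001L, 4001L))
  for (i in 1:20) {
    for (s in 1:3) {
      rng <- (2000 * (s - 1) + 1):(2000 * s)
      expect_identical(mo$dosages[i, rng], f$dosages[mo$ledger[i, s], rng])
    }
  }
  # a short trailing segment is handled
  spec2 <- simulation_spec(n_founders = 5, n_samples = 4, m_markers = 4500,
                           segment_len = 2000, n_causal = 2, seed = 8)
  mo2 <- mosaic_individuals(make_founders(spec2), spec2)
  expect_equal(mo2$segment_starts, c(1L, 2001L, 4001L))
  expect_equal(ncol(mo2$ledger), 3L)
})

test_that("trait generation honors the heritability and prevalence contracts", {
  spec <- simulation_spec(n_samples = 1000, m_markers = 1000, h2 = 0.5,
                          segment_len = 500, n_causal = 25,
                          trait_kind = "binary", prevalence = 0.1, seed = 5)
  ds <- simulate_dataset(spec)
  expect_equal(sum(ds$truth$phenotype == 1), 100L)
  expect_equal(ds$truth$realized_h2,
               var(ds$truth$genetic_values) / var(ds$truth$liability),
               tolerance = 1e-12)

  spec1 <- simulation_spec(n_samples = 200, m_markers = 500, h2 = 1,
                           segment_len = 250, n_causal = 10, seed = 6)
  t1 <- simulate_trait(mosaic_individuals(make_founders(spec1), spec1)$dosages,
                       spec1)
  expect_equal(t1$noise, rep(0, 200))
  expect_equal(t1$realized_h2, 1)

  spec0 <- simulation_spec(n_samples = 200, m_markers = 500, h2 = 0,
                           segment_len = 250, n_causal = 10, seed = 6)
  t0 <- simulate_trait(mosaic_individuals(make_founders(spec0), spec0)$dosages,
                       spec0)
  expect_equal(t0$genetic_values, rep(0, 200))
  expect_error(simulation_spec(h2 = 1.5), "h2")
})

test_that("realized heritability stays near its target across seeds", {
  r <- vapply(1:5, function(s) {
    spec <- simulation_spec(n_samples = 2000, m_markers = 5000, h2 = 0.5,
                            n_causal = 25, seed = 500 + s)
    simulate_dataset(spec)$truth$realized_h2
  }, numeric(1))
  expect_true(all(abs(r - 0.5) < 0.12))
})

test_that("identical specs produce byte-identical datasets", {
  spec <- simulation_spec(n_samples = 30, m_markers = 400, segment_len = 100,
                          n_causal = 5, seed = 11)
  p1 <- tempfile("d1"); p2 <- tempfile("d2")
  ds1 <- simulate_dataset(spec)
  ds2 <- simulate_dataset(spec)
  write_dataset(ds1$mosaic$dosages, ds1$truth, spec, p1,
                ledger = ds1$mosaic$ledger)
  write_dataset(ds2$mosaic$dosages, ds2$truth, spec, p2,
                ledger = ds2$mosaic$ledger)
  for (ext in c(".bed", ".bim", ".fam", ".pheno.tsv", ".truth.tsv",
                ".ledger.tsv")) {
    expect_identical(readBin(paste0(p1, ext), "raw", 1e6),
                     readBin(paste0(p2, ext), "raw", 1e6), label = ext)
  }
  # and the files parse back to the same dosages
  expect_identical(read_dosages(open_bed(p1)), unname(ds1$mosaic$dosages))
  truth <- read.table(paste0(p1, ".truth.tsv"), header = TRUE)
  expect_equal(nrow(truth), 5L)
  fam <- read.table(paste0(p1, ".fam"))
  expect_true(all(fam$V6 == -9))
})

test_that("related sibships show elevated genomic relatedness", {
  ok <- vapply(1:10, function(s) {
    spec <- simulation_spec(n_founders = 50, n_samples = 200, m_markers = 2000,
                            segment_len = 200, related_fraction = 0.5,
                            ancestors_per_related = 2, sibship_size = 2,
                            n_causal = 5, seed = 600 + s)
    ds <- simulate_dataset(spec)
    d <- ds$mosaic$dosages
    p <- colMeans(d) / 2
    keep <- p > 0 & p < 1
    W <- sweep(d[, keep], 2, 2 * p[keep])
    W <- sweep(W, 2, sqrt(2 * p[keep] * (1 - p[keep])), "/")
    G <- tcrossprod(W) / sum(keep)
    sib <- ds$mosaic$sibship
    rel_pairs <- which(outer(sib, sib, function(a, b) !is.na(a) & !is.na(b) & a == b) &
                         upper.tri(G), arr.ind = TRUE)
    unrel <- is.na(sib)
    unrel_pairs <- which(outer(unrel, unrel, "&") & upper.tri(G), arr.ind = TRUE)
    mean(G[rel_pairs]) > mean(G[unrel_pairs])
  }, logical(1))
  expect_true(all(ok))
})
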