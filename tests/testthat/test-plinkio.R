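# PLINK binary codec, genotype streaming and phenotype/covariate input.

test_that("BED round-trip is the identity over all two-bit codes", {
  # every code in every byte slot: 4 samples x 4 markers covers all offsets
  d4 <- rbind(c(0L, 1L, 2L, NA), c(2L, NA, 0L, 1L),
              c(1L, 2L, NA, 0L), c(NA, 0L, 1L, 2L))
  src <- toy_source(d4)
  expect_equal(src$n, 4L)
  expect_equal(src$m, 4L)
  expect_identical(read_dosages(src), d4)

  # random 50 x 200 with missing, odd n so padding bits are exercised
  d <- rand_dosages(51, 200, miss_rate = 0.05, seed = 9)
  src2 <- toy_source(d)
  expect_identical(read_dosages(src2), d)

  # single sample, single marker: 3-byte header + 1 payload byte
  pre <- tempfile("one")
  write_bed(matrix(2L, 1, 1), toy_variants(1), toy_samples(1), pre)
  expect_equal(file.size(paste0(pre, ".bed")), 4)
  expect_identical(read_dosages(open_bed(pre)), matrix(2L, 1, 1))
})

test_that("malformed BED files are rejected with informative errors", {
  d <- rand_dosages(4, 3)
  pre <- tempfile("bad")
  write_bed(d, toy_variants(3), toy_samples(4), pre)

  bed <- paste0(pre, ".bed")
  raw <- readBin(bed, "raw", file.size(bed))

  bad1 <- raw; bad1[1] <- as.raw(0x00)
  writeBin(bad1, bed)
  expect_error(open_bed(pre), "magic")

  bad2 <- raw; bad2[3] <- as.raw(0x00) # individual-major mode
  writeBin(bad2, bed)
  expect_error(open_bed(pre), "SNP-major")

  writeBin(c(raw, as.raw(0)), bed) # payload too long
  expect_error(open_bed(pre), "length mismatch")

  writeBin(raw, bed)
  expect_error(open_bed(tempfile("nothere")), "file not found")
  expect_error(write_bed(matrix(integer(0), 4, 0), toy_variants(0),
                         toy_samples(4), pre), "empty variant")
  expect_error(write_bed(matrix(0L, 4, 3), toy_variants(2),
                         toy_samples(4), pre), "dimension mismatch")
})

test_that("allele statistics flag all-missing markers and match hand counts", {
  d <- cbind(c(0L, 1L, 2L, 1L), rep(NA_integer_, 4), c(2L, 2L, NA, 0L))
  src <- toy_source(d)
  st <- allele_stats(src)
  expect_equal(st$miss_frac, c(0, 1, 0.25))
  expect_equal(st$p[1], 4 / 8)       # mean dosage / 2 over observed
  expect_true(is.na(st$p[2]))
  expect_equal(st$p[3], 4 / 6)
})

test_that("normalization matches the binomial closed form and drops bad markers", {
  # dosages (0,1,2,1) at p = 0.5 -> (-sqrt(2), 0, sqrt(2), 0)
  d <- cbind(c(0L, 1L, 2L, 1L),  # the hand-computed column
             c(2L, 2L, 2L, 2L),  # monomorphic: dropped
             c(0L, 0L, 2L, 2L))
  src <- toy_source(d)
  ng <- normalized_genotypes(src)
  expect_equal(ng$variant_idx, c(1L, 3L))
  expect_equal(ng$Z[, 1], c(-sqrt(2), 0, sqrt(2), 0), tolerance = 1e-12)

  # block partition arithmetic: 10 retained markers at block_size 4
  d10 <- rand_dosages(30, 10, seed = 4)
  d10[1, ] <- 0L; d10[2, ] <- 1L  # guarantee polymorphism
  src10 <- toy_source(d10)
  it <- stream_blocks(src10, block_size = 4)
  widths <- integer(0)
  while (!is.null(b <- it())) widths <- c(widths, ncol(b$data))
  expect_equal(widths, c(4L, 4L, 2L))
  expect_error(stream_blocks(src10, block_size = 0), "positive")
})

test_that("streamed blocks are invariant to block size and exactly centered", {
  d <- rand_dosages(40, 57, miss_rate = 0.08, seed = 11)
  src <- toy_source(d)
  full <- normalized_genotypes(src, block_size = 1000)$Z
  for (bs in c(1, 3, 7, 57)) {
    expect_equal(normalized_genotypes(src, block_size = bs)$Z, full,
                 tolerance = 1e-12)
  }
  expect_lt(max(abs(colMeans(full))), 1e-8)

  # on complete data the streamed matrix equals the closed-form oracle,
  # including its per-column sample variance
  dc <- rand_dosages(60, 30, miss_rate = 0, seed = 12)
  srcc <- toy_source(dc)
  ora <- normalize_oracle(dc)
  got <- normalized_genotypes(srcc)
  expect_equal(got$variant_idx, ora$keep)
  expect_equal(got$Z, ora$Z, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(apply(got$Z, 2, var), apply(ora$Z, 2, var), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("phenotype input aligns by key, normalizes, and flags bad values", {
  d <- rand_dosages(4, 3, seed = 2)
  src <- toy_source(d)
  ids <- data.frame(FID = src$samples$fid, IID = src$samples$iid)

  p1 <- tempfile(fileext = ".tsv")
  write.table(cbind(ids, Y = 1:4), p1, quote = FALSE, row.names = FALSE)
  y <- read_phenotype(p1, src)
  expect_equal(mean(y), 0, tolerance = 1e-12)
  expect_equal(var(y), 1, tolerance = 1e-12)

  # shuffled rows give the identical aligned vector
  p2 <- tempfile(fileext = ".tsv")
  write.table(cbind(ids, Y = 1:4)[c(3, 1, 4, 2), ], p2, quote = FALSE,
              row.names = FALSE)
  expect_equal(read_phenotype(p2, src), y)

  # missing codes: -9 and absent samples come back as NA
  p3 <- tempfile(fileext = ".tsv")
  write.table(cbind(ids, Y = c(-9, 2, 3, 4))[1:3, ], p3, quote = FALSE,
              row.names = FALSE)
  y3 <- read_phenotype(p3, src)
  expect_true(is.na(y3[1]) && is.na(y3[4]))
  expect_equal(attr(y3, "n_missing"), 2L)

  p4 <- tempfile(fileext = ".tsv")
  write.table(cbind(ids, Y = rep(7, 4)), p4, quote = FALSE, row.names = FALSE)
  expect_error(read_phenotype(p4, src), "zero variance")

  p5 <- tempfile(fileext = ".tsv")
  writeLines(c("FID IID Y", "F1 I1 1.0", "F2 I2 oops", "F3 I3 3", "F4 I4 4"), p5)
  expect_error(read_phenotype(p5, src), "line 3")

  p6 <- tempfile(fileext = ".tsv")
  write.table(data.frame(FID = "X", IID = "X", Y = 1), p6, quote = FALSE,
              row.names = FALSE)
  expect_error(read_phenotype(p6, src), "no overlapping samples")
})

test_that("covariate input aligns multi-column data and rejects holes", {
  d <- rand_dosages(4, 3, seed = 5)
  src <- toy_source(d)
  ids <- data.frame(FID = src$samples$fid, IID = src$samples$iid)

  c1 <- tempfile(fileext = ".tsv")
  write.table(cbind(ids, AGE = c(30, 40, 50, 60), SEX = c(1, 2, 1, 2))[c(2, 4, 1, 3), ],
              c1, quote = FALSE, row.names = FALSE)
  X <- read_covariates(c1, src)
  expect_equal(dim(X), c(4L, 2L))
  expect_equal(X[, "AGE"], c(30, 40, 50, 60))

  c2 <- tempfile(fileext = ".tsv")
  writeLines(c("FID IID AGE", "F1 I1 30", "F2 I2 NA", "F3 I3 50", "F4 I4 60"), c2)
  expect_error(read_covariates(c2, src), "line 3.*AGE")

  # zero covariate columns after the keys is accepted
  c3 <- tempfile(fileext = ".tsv")
  write.table(ids, c3, quote = FALSE, row.names = FALSE)
  expect_equal(ncol(read_covariates(c3, src)), 0L)
})
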