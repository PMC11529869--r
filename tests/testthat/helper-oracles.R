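# Independent oracles and fixture builders shared across test files.
# Oracles use dense linear algebra (explicit V, solve/determinant, full SVD,
# grid searches) and never call the streaming/eigen code paths they check.

# random hard-call dosage matrix, optionally with missing entries
rand_dosages <- function(n, m, miss_rate = 0, seed = 1) {
  set.seed(seed)
  d <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  if (miss_rate > 0) d[runif(n * m) < miss_rate] <- NA_integer_
  d
}

toy_variants <- function(m) {
  data.frame(chrom = "1", id = sprintf("snp%d", seq_len(m)), cm = 0,
             bp = seq_len(m), a1 = "A", a2 = "B", stringsAsFactors = FALSE)
}

toy_samples <- function(n) {
  data.frame(fid = sprintf("F%d", seq_len(n)), iid = sprintf("I%d", seq_len(n)),
             sex = 0L, pheno_slot = -9, stringsAsFactors = FALSE)
}

# write a dosage matrix as a PLINK fileset in tempdir and open it
toy_source <- function(dosages, prefix = tempfile("fix")) {
  write_bed(dosages, toy_variants(ncol(dosages)), toy_samples(nrow(dosages)),
            prefix)
  open_bed(prefix)
}

# hand normalization: impute to 2p, center, scale (complete-data closed form)
normalize_oracle <- function(d) {
  p <- colMeans(d, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1 & pmin(p, 1 - p) >= 0.01
  x <- d[, keep, drop = FALSE]
  p <- p[keep]
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    v[is.na(v)] <- 2 * p[j]
    x[, j] <- (v - 2 * p[j]) / sqrt(2 * p[j] * (1 - p[j]))
  }
  list(Z = x, keep = which(keep), p = p)
}

# dense profiled (restricted) log-likelihood via explicit V, solve and
# determinant -- no eigendecomposition
dense_profile_ll <- function(tau, H0, y, X, mode = "REML") {
  s1 <- length(y)
  H <- H0 + tau * diag(s1)
  Hi <- solve(H)
  k <- if (is.null(X)) 0L else ncol(X)
  if (k > 0L) {
    A <- t(X) %*% Hi %*% X
    beta <- solve(A, t(X) %*% Hi %*% y)
    r <- y - drop(X %*% beta)
  } else {
    r <- y
  }
  Q <- drop(t(r) %*% Hi %*% r)
  ld <- determinant(H, logarithm = TRUE)$modulus[1L]
  if (mode == "ML") {
    nn <- s1
    extra <- 0
  } else {
    nn <- s1 - k
    extra <- determinant(A, logarithm = TRUE)$modulus[1L]
  }
  sg2 <- Q / nn
  list(value = -0.5 * (nn * log(2 * pi * sg2) + ld + extra + nn),
       sigma_g2 = sg2)
}

# brute-force variance fit: dense grid on log tau + golden-section refinement
dense_fit <- function(H0, y, X, mode = "REML", grid_n = 400) {
  thetas <- seq(log(1e-6), log(1e6), length.out = grid_n)
  vals <- vapply(thetas, function(th)
    dense_profile_ll(exp(th), H0, y, X, mode)$value, numeric(1))
  i <- which.max(vals)
  lo <- thetas[max(1L, i - 1L)]
  hi <- thetas[min(grid_n, i + 1L)]
  opt <- stats::optimize(function(th)
    dense_profile_ll(exp(th), H0, y, X, mode)$value,
    interval = c(lo, hi), maximum = TRUE, tol = 1e-10)
  tau <- exp(opt$maximum)
  f <- dense_profile_ll(tau, H0, y, X, mode)
  list(tau = tau, sigma_g2 = f$sigma_g2, loglik = opt$objective)
}

# brute-force chi-squared scan with explicit V and its dense inverse
dense_scan <- function(Z, y, X, tau, sigma_g2, H0) {
  V <- sigma_g2 * (H0 + tau * diag(length(y)))
  Vi <- solve(V)
  if (!is.null(X) && ncol(X) > 0L) {
    A <- t(X) %*% Vi %*% X
    Py <- y - drop(X %*% solve(A, t(X) %*% Vi %*% y))
    PZ <- Z - X %*% solve(A, t(X) %*% Vi %*% Z)
  } else {
    Py <- y
    PZ <- Z
  }
  num <- drop(t(PZ) %*% Vi %*% Py)
  den <- colSums(PZ * (Vi %*% PZ))
  num^2 / den
}

# Hudson FST estimator (ratio of averages) from two finite allele-frequency
# samples; n1, n2 are allele counts (2 x individuals)
hudson_fst <- function(p1, p2, n1, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# variance_components stub for closed-form operator tests
vc_stub <- function(tau, sigma_g2, mode = "REML") {
  structure(list(tau = tau, sigma_g2 = sigma_g2, sigma_e2 = tau * sigma_g2,
                 h2 = 1 / (1 + tau), beta = numeric(0), loglik = NA_real_,
                 iterations = 0L, converged = TRUE, mode = mode),
            class = "variance_components")
}

# run the full pipeline on an in-memory simulated dataset
run_pipeline_on <- function(ds, sample_sketch = 0.1, marker_sketch = 0.5,
                            seed = 1, mode = "REML", num_pcs = 10) {
  pre <- tempfile("ds")
  write_dataset(ds$mosaic$dosages, ds$truth, ds$spec, pre)
  on.exit(unlink(paste0(pre, c(".bed", ".bim", ".fam", ".pheno.tsv",
                               ".truth.tsv"))))
  out <- tempfile("run")
  r <- suppressMessages(run_assoc(assoc_config(
    bfile = pre, pheno = paste0(pre, ".pheno.tsv"),
    sample_sketch = sample_sketch, marker_sketch = marker_sketch,
    seed = seed, mode = mode, num_pcs = num_pcs, out = out)))
  unlink(paste0(out, c(".assoc.tsv", ".fit.txt", ".manifest.json")))
  r
}
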