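# PLINK 1 binary (BED/BIM/FAM) input/output and genotype normalization.
#
# The BED payload is SNP-major: each marker occupies ceiling(n/4) bytes, four
# two-bit genotype codes per byte, lowest-order bits first. Code map (PLINK
# 1.9, counting copies of allele A1): 0b00 = 2, 0b10 = 1, 0b11 = 0,
# 0b01 = missing.

.BED_MAGIC <- as.raw(c(0x6c, 0x1b))
.BED_SNP_MAJOR <- as.raw(0x01)

# byte-value -> 4 dosages lookup, built once at load
.bed_decode_lut <- local({
  map <- c(2L, NA_integer_, 1L, 0L) # two-bit codes 0b00, 0b01, 0b10, 0b11
  lut <- matrix(NA_integer_, nrow = 256L, ncol = 4L)
  for (b in 0:255) {
    for (k in 0:3) {
      code <- bitwAnd(bitwShiftR(b, 2L * k), 3L)
      lut[b + 1L, k + 1L] <- map[code + 1L]
    }
  }
  lut
})

# dosage -> two-bit code (index 1 = dosage 0); NA handled separately
.bed_encode_map <- c(3L, 2L, 0L)

#' Normalization policy for genotype streaming
#'
#' Controls which markers are retained and how hard-call dosages are turned
#' into the normalized columns used by the sketched LMM. Missing genotypes
#' are imputed to the marker mean `2p`, columns are centered at `2p` and
#' scaled by `sqrt(2p(1-p))` (the binomial unit-variance convention, which
#' makes `diag(Z Z^T / m)` approximately 1). Markers with minor allele
#' frequency below `maf_min`, or with zero variance, are excluded before any
#' sketching.
#'
#' @param maf_min Minimum minor allele frequency in `[0, 0.5)`; markers below
#'   it are dropped. Default 0.01.
#' @return An object of class `normalization_policy`.
#' @export
normalization_policy <- function(maf_min = 0.01) {
  if (!is.numeric(maf_min) || length(maf_min) != 1L || is.na(maf_min) ||
      maf_min < 0 || maf_min >= 0.5) {
    stop("`maf_min` must be a single value in [0, 0.5)")
  }
  structure(
    list(maf_min = maf_min,
         missing_rule = "impute-to-mean",
         scale_rule = "unit-variance-binomial"),
    class = "normalization_policy"
  )
}

#' Open a PLINK binary fileset
#'
#' Parses `prefix.bim` and `prefix.fam`, validates the `prefix.bed` header
#' (magic bytes `0x6C 0x1B`, SNP-major mode byte `0x01`) and payload length,
#' and returns a lightweight handle. The genotype payload itself is never
#' loaded; it is streamed on demand by [stream_blocks()] and
#' [read_dosages()]. Per-marker allele statistics are computed lazily on
#' first use and cached.
#'
#' @param prefix Path stem; `prefix.bed`, `prefix.bim` and `prefix.fam` must
#'   all exist.
#' @return A `genotype_source` with fields `n`, `m`, `variants` (data frame
#'   with columns `chrom`, `id`, `cm`, `bp`, `a1`, `a2`) and `samples`
#'   (columns `fid`, `iid`, `sex`, `pheno_slot`).
#' @export
open_bed <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  for (p in paths) {
    if (!file.exists(p)) stop("file not found: ", p)
  }

  bim <- utils::read.table(paths[2L], header = FALSE, stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  names(bim) <- c("chrom", "id", "cm", "bp", "a1", "a2")
  if (any(!nzchar(bim$id))) stop("BIM contains empty variant ids: ", paths[2L])
  if (any(bim$bp < 0)) stop("BIM contains negative positions: ", paths[2L])

  fam <- utils::read.table(paths[3L], header = FALSE, stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "character",
                                          "character", "integer", "numeric"))
  names(fam) <- c("fid", "iid", "pat", "mat", "sex", "pheno_slot")
  key <- paste(fam$fid, fam$iid, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (FID, IID) pairs in ", paths[3L])
  }

  n <- nrow(fam)
  m <- nrow(bim)
  hdr <- readBin(paths[1L], what = "raw", n = 3L)
  if (length(hdr) < 3L || !identical(hdr[1:2], .BED_MAGIC)) {
    stop("not a PLINK BED file (bad magic bytes): ", paths[1L])
  }
  if (!identical(hdr[3L], .BED_SNP_MAJOR)) {
    stop("unsupported BED mode byte (only SNP-major 0x01 is supported): ",
         paths[1L])
  }
  expected <- ceiling(n / 4) * m
  actual <- file.size(paths[1L]) - 3
  if (actual != expected) {
    stop(sprintf(
      "BED payload length mismatch in %s: expected %d bytes for n=%d, m=%d, found %d",
      paths[1L], expected, n, m, actual))
  }

  structure(
    list(prefix = prefix, bed_path = paths[1L], n = n, m = m,
         variants = bim,
         samples = fam[, c("fid", "iid", "sex", "pheno_slot")],
         cache = new.env(parent = emptyenv())),
    class = "genotype_source"
  )
}

#' @export
print.genotype_source <- function(x, ...) {
  cat(sprintf("genotype_source: %d samples x %d markers (%s)\n",
              x$n, x$m, x$prefix))
  invisible(x)
}

#' Read raw hard-call dosages from a genotype source
#'
#' Decodes the SNP-major two-bit payload for a range of markers into an
#' integer matrix of allele-A1 dosages in `{0, 1, 2}` with `NA` for missing.
#'
#' @param source A `genotype_source` from [open_bed()].
#' @param markers Optional integer vector of 1-based marker indices
#'   (default: all markers). Must be sorted and unique.
#' @return An `n x length(markers)` integer matrix.
#' @export
read_dosages <- function(source, markers = NULL) {
  stopifnot(inherits(source, "genotype_source"))
  if (is.null(markers)) markers <- seq_len(source$m)
  if (length(markers) == 0L) {
    return(matrix(integer(0), nrow = source$n, ncol = 0L))
  }
  if (is.unsorted(markers, strictly = TRUE) ||
      markers[1L] < 1L || markers[length(markers)] > source$m) {
    stop("`markers` must be strictly increasing indices in [1, m]")
  }
  n <- source$n
  bpm <- ceiling(n / 4) # bytes per marker
  con <- file(source$bed_path, "rb")
  on.exit(close(con))

  # read maximal contiguous runs in single seeks
  runs <- split(markers, cumsum(c(1L, diff(markers) != 1L)))
  out <- matrix(NA_integer_, nrow = n, ncol = length(markers))
  col0 <- 0L
  for (run in runs) {
    lo <- run[1L]
    nm <- length(run)
    seek(con, where = 3 + (lo - 1) * bpm, origin = "start")
    bytes <- readBin(con, what = "raw", n = nm * bpm)
    if (length(bytes) != nm * bpm) stop("truncated BED payload: ", source$bed_path)
    dec <- .bed_decode_lut[as.integer(bytes) + 1L, , drop = FALSE]
    dec <- t(dec)                       # 4 x (bpm*nm), slot-major per byte
    dim(dec) <- c(4L * bpm, nm)
    out[, col0 + seq_len(nm)] <- dec[seq_len(n), , drop = FALSE]
    col0 <- col0 + nm
  }
  out
}

#' Per-marker allele statistics
#'
#' Computes (and caches, for the full sample set) the allele-A1 frequency
#' `p = mean(dosage)/2` over non-missing calls and the missing-call fraction
#' for every marker, streaming the BED payload in blocks. A marker with all
#' calls missing gets `p = NA` and missing fraction 1.
#'
#' @param source A `genotype_source`.
#' @param samples Optional integer indices of the samples over which to
#'   compute statistics (default: all).
#' @param block_size Markers decoded per streaming pass.
#' @return Data frame with columns `p` and `miss_frac`, one row per marker.
#' @export
allele_stats <- function(source, samples = NULL, block_size = 2048L) {
  stopifnot(inherits(source, "genotype_source"))
  full <- is.null(samples)
  if (full && !is.null(source$cache$allele_stats)) {
    return(source$cache$allele_stats)
  }
  idx <- if (full) seq_len(source$n) else as.integer(samples)
  m <- source$m
  p <- numeric(m)
  miss <- numeric(m)
  lo <- 1L
  while (lo <= m) {
    hi <- min(lo + block_size - 1L, m)
    d <- read_dosages(source, lo:hi)[idx, , drop = FALSE]
    nmiss <- colSums(is.na(d))
    nobs <- length(idx) - nmiss
    s <- colSums(d, na.rm = TRUE)
    p[lo:hi] <- ifelse(nobs > 0, s / (2 * nobs), NA_real_)
    miss[lo:hi] <- nmiss / length(idx)
    lo <- hi + 1L
  }
  res <- data.frame(p = p, miss_frac = miss)
  if (full) source$cache$allele_stats <- res
  res
}

# Indices of markers that survive the policy filter (MAF, zero variance,
# all-missing) for a given sample subset.
retained_markers <- function(source, policy, samples = NULL) {
  st <- allele_stats(source, samples = samples)
  ok <- !is.na(st$p) & st$p > 0 & st$p < 1 &
    pmin(st$p, 1 - st$p) >= policy$maf_min
  which(ok)
}

#' Stream normalized genotype blocks
#'
#' Returns an iterator over contiguous blocks of the normalized genotype
#' matrix so the full matrix never needs to reside in memory. Each call to
#' the returned function yields the next block, or `NULL` when exhausted.
#' Retained markers (see [normalization_policy()]) are covered exactly once,
#' in BIM order. Within a block, missing dosages are imputed to `2p`, and
#' each column is transformed to `(g - 2p) / sqrt(2p(1 - p))`, where `p` is
#' the allele frequency computed on the streamed samples; every normalized
#' column therefore has mean exactly 0 on those samples.
#'
#' @param source A `genotype_source`.
#' @param policy A [normalization_policy()].
#' @param block_size Number of retained markers per block (>= 1).
#' @param samples Optional integer indices of samples to stream (default all);
#'   allele frequencies are recomputed on the subset.
#' @return A function; each call returns `list(data, marker_range,
#'   variant_idx)` where `data` is the `n_used x b` normalized block,
#'   `marker_range` is the 0-based half-open interval into the retained
#'   marker list, and `variant_idx` gives 1-based indices into
#'   `source$variants` — or `NULL` after the last block.
#' @export
stream_blocks <- function(source, policy = normalization_policy(),
                          block_size = 1024L, samples = NULL) {
  stopifnot(inherits(source, "genotype_source"),
            inherits(policy, "normalization_policy"))
  if (!is.numeric(block_size) || length(block_size) != 1L || block_size < 1) {
    stop("`block_size` must be a positive integer")
  }
  block_size <- as.integer(block_size)
  idx <- if (is.null(samples)) seq_len(source$n) else as.integer(samples)
  st <- allele_stats(source, samples = samples)
  keep <- retained_markers(source, policy, samples = samples)
  pkeep <- st$p[keep]
  nret <- length(keep)
  pos <- 0L # retained markers emitted so far

  function() {
    if (pos >= nret) return(NULL)
    lo <- pos + 1L
    hi <- min(pos + block_size, nret)
    vidx <- keep[lo:hi]
    d <- read_dosages(source, vidx)[idx, , drop = FALSE]
    p <- pkeep[lo:hi]
    center <- 2 * p
    scale <- sqrt(2 * p * (1 - p))
    # impute missing to the column mean, then center and scale
    x <- sweep(d, 2L, center)
    x[is.na(x)] <- 0
    x <- sweep(x, 2L, scale, "/")
    pos <<- hi
    list(data = x, marker_range = c(lo - 1L, hi), variant_idx = vidx)
  }
}

# Assemble the full normalized matrix (test/oracle convenience; small data
# only). Equivalent to concatenating all stream_blocks() outputs.
#' Materialize the full normalized genotype matrix
#'
#' Convenience wrapper that concatenates every block from [stream_blocks()].
#' Intended for small data and for oracle comparisons; production paths
#' stream instead.
#'
#' @inheritParams stream_blocks
#' @return List with `Z` (`n_used x m_retained` matrix) and `variant_idx`.
#' @export
normalized_genotypes <- function(source, policy = normalization_policy(),
                                 samples = NULL, block_size = 2048L) {
  it <- stream_blocks(source, policy, block_size = block_size,
                      samples = samples)
  blocks <- list()
  vidx <- integer(0)
  while (!is.null(b <- it())) {
    blocks[[length(blocks) + 1L]] <- b$data
    vidx <- c(vidx, b$variant_idx)
  }
  nr <- if (is.null(samples)) source$n else length(samples)
  Z <- if (length(blocks)) do.call(cbind, blocks) else
    matrix(numeric(0), nrow = nr, ncol = 0L)
  list(Z = Z, variant_idx = vidx)
}

#' Write a PLINK binary fileset
#'
#' Encodes an integer dosage matrix (allele-A1 copies in `{0, 1, 2}`, `NA`
#' missing) as a SNP-major BED file with matching BIM and FAM. Reading the
#' files back with [open_bed()] and [read_dosages()] reproduces the dosage
#' matrix exactly.
#'
#' @param dosages `n x m` integer matrix.
#' @param variants Data frame with columns `chrom`, `id`, `cm`, `bp`, `a1`,
#'   `a2` (`m` rows).
#' @param samples Data frame with columns `fid`, `iid` and optionally `sex`,
#'   `pheno_slot` (`n` rows).
#' @param prefix Output path stem.
#' @return `prefix`, invisibly.
#' @export
write_bed <- function(dosages, variants, samples, prefix) {
  dosages <- as.matrix(dosages)
  n <- nrow(dosages)
  m <- ncol(dosages)
  if (m == 0L || is.null(variants) || nrow(variants) == 0L) {
    stop("empty variant list")
  }
  if (n == 0L) stop("empty sample list")
  if (nrow(variants) != m) {
    stop(sprintf("dimension mismatch: %d dosage columns but %d variants",
                 m, nrow(variants)))
  }
  if (nrow(samples) != n) {
    stop(sprintf("dimension mismatch: %d dosage rows but %d samples",
                 n, nrow(samples)))
  }
  vals <- dosages[!is.na(dosages)]
  if (length(vals) && !all(vals %in% 0:2)) {
    stop("dosages must be in {0, 1, 2} or NA")
  }
  if (is.null(samples$sex)) samples$sex <- 0L
  if (is.null(samples$pheno_slot)) samples$pheno_slot <- -9

  # encode: dosage -> two-bit code; pad sample dimension to a multiple of 4
  codes <- matrix(0L, nrow = 4L * ceiling(n / 4), ncol = m) # pad bits are zero
  dc <- matrix(.bed_encode_map[dosages + 1L], nrow = n, ncol = m)
  dc[is.na(dosages)] <- 1L
  codes[seq_len(n), ] <- dc
  dim(codes) <- c(4L, length(codes) / 4L)
  bytes <- as.raw(codes[1L, ] + 4L * codes[2L, ] +
                    16L * codes[3L, ] + 64L * codes[4L, ])

  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(c(.BED_MAGIC, .BED_SNP_MAJOR, bytes), con)
  close(con)

  utils::write.table(
    variants[, c("chrom", "id", "cm", "bp", "a1", "a2")],
    paste0(prefix, ".bim"),
    quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = samples$fid, iid = samples$iid,
                    pat = 0L, mat = 0L, sex = samples$sex,
                    pheno = samples$pheno_slot)
  utils::write.table(fam, paste0(prefix, ".fam"),
                     quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

# Parse a whitespace-delimited FID/IID-keyed table; detects an optional
# header whose first two fields are FID and IID (case-insensitive).
.read_keyed_table <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first)) stop("empty file: ", path)
  toks <- strsplit(trimws(first), "[ \t]+")[[1]]
  has_header <- length(toks) >= 2L &&
    toupper(toks[1L]) == "FID" && toupper(toks[2L]) == "IID"
  tab <- utils::read.table(path, header = has_header,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("expected at least FID and IID columns: ", path)
  if (!has_header) {
    names(tab)[1:2] <- c("FID", "IID")
    if (ncol(tab) > 2L) {
      names(tab)[-(1:2)] <- paste0("V", seq_len(ncol(tab) - 2L))
    }
  }
  list(tab = tab, has_header = has_header)
}

#' Read and normalize a phenotype vector
#'
#' Reads a whitespace-delimited phenotype file (first two columns FID and
#' IID, optional header), joins it to the sample order of a genotype source,
#' and returns the phenotype mean-centered and scaled to unit variance over
#' the observed samples. The value `-9` and the string `NA` are treated as
#' missing; samples absent from the file are likewise missing. Missing
#' entries are returned as `NA` and are expected to be dropped by the caller
#' before sketching.
#'
#' @param path Phenotype file path.
#' @param source A `genotype_source` giving the target sample order.
#' @param column Which phenotype to use: a column name (requires a header) or
#'   a 1-based index among the columns after FID/IID. Default: the first.
#' @return Numeric vector of length `source$n` (normalized, `NA` = missing)
#'   with attribute `n_missing`.
#' @export
read_phenotype <- function(path, source, column = 1L) {
  stopifnot(inherits(source, "genotype_source"))
  kt <- .read_keyed_table(path)
  tab <- kt$tab
  vals_cols <- names(tab)[-(1:2)]
  if (length(vals_cols) == 0L) stop("no phenotype columns in ", path)
  if (is.character(column)) {
    if (!(column %in% vals_cols)) {
      stop("phenotype column not found: ", column)
    }
    cname <- column
  } else {
    column <- as.integer(column)
    if (column < 1L || column > length(vals_cols)) {
      stop("phenotype column index out of range: ", column)
    }
    cname <- vals_cols[column]
  }

  raw <- tab[[cname]]
  num <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(num) & !(toupper(raw) %in% c("NA", "NAN")))
  if (length(bad)) {
    stop(sprintf("non-numeric phenotype value %s at line %d of %s",
                 raw[bad[1L]], bad[1L] + as.integer(kt$has_header), path))
  }
  num[!is.na(num) & num == -9] <- NA_real_

  file_key <- paste(tab[[1L]], tab[[2L]], sep = "\r")
  src_key <- paste(source$samples$fid, source$samples$iid, sep = "\r")
  pos <- match(src_key, file_key)
  if (all(is.na(pos))) {
    stop("no overlapping samples between ", path, " and the genotype source")
  }
  y <- num[pos] # NA where sample absent from file

  obs <- !is.na(y)
  if (sum(obs) < 2L) stop("fewer than two observed phenotypes after alignment")
  s <- stats::sd(y[obs])
  if (!is.finite(s) || s == 0) {
    stop("phenotype has zero variance after alignment")
  }
  y <- (y - mean(y[obs])) / s
  attr(y, "n_missing") <- sum(!obs)
  y
}

#' Read a covariate matrix
#'
#' Reads a whitespace-delimited covariate file (first two columns FID and
#' IID, optional header) and aligns its remaining numeric columns to the
#' sample order of a genotype source. Every source sample must be present
#' and every covariate cell non-missing.
#'
#' @param path Covariate file path.
#' @param source A `genotype_source`.
#' @return Numeric `n x c` matrix with column names (possibly `c = 0`).
#' @export
read_covariates <- function(path, source) {
  stopifnot(inherits(source, "genotype_source"))
  kt <- .read_keyed_table(path)
  tab <- kt$tab
  cn <- names(tab)[-(1:2)]

  file_key <- paste(tab[[1L]], tab[[2L]], sep = "\r")
  src_key <- paste(source$samples$fid, source$samples$iid, sep = "\r")
  pos <- match(src_key, file_key)
  if (all(is.na(pos))) {
    stop("no overlapping samples between ", path, " and the genotype source")
  }
  if (anyNA(pos)) {
    miss <- which(is.na(pos))[1L]
    stop(sprintf("sample (%s, %s) missing from covariate file %s",
                 source$samples$fid[miss], source$samples$iid[miss], path))
  }
  X <- matrix(NA_real_, nrow = source$n, ncol = length(cn),
              dimnames = list(NULL, cn))
  hdr_off <- as.integer(kt$has_header)
  for (j in seq_along(cn)) {
    raw <- tab[[cn[j]]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num))
    if (length(bad)) {
      stop(sprintf("missing or non-numeric covariate at line %d, column %s of %s",
                   bad[1L] + hdr_off, cn[j], path))
    }
    X[, j] <- num[pos]
  }
  X
}
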