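# Seeded Gaussian sketch operators and streaming sketched products.
#
# A sample sketch S1 (s1 x n) left-multiplies the normalized genotypes; a
# marker sketch S2 (m x s2) right-multiplies them inside the GRM. Entries are
# i.i.d. N(0, 1/s) where s is the sketch (output) dimension. Each global
# index along the long axis (sample column of S1, marker row of S2) owns its
# own RNG substream, keyed by a deterministic mix of the user seed, the
# index and an orientation salt, so any block partition or request order
# materializes identical entries.

.SKETCH_MOD <- 2147483629 # largest prime below 2^31

.sketch_index_seed <- function(seed, index, salt) {
  # exact in double precision: all intermediates < 2^53
  (((seed %% .SKETCH_MOD) * 48271 + index * 16807 + salt * 69621) %% .SKETCH_MOD)
}

#' Construct a sketch operator
#'
#' Creates a seeded random-projection operator with i.i.d. Gaussian entries
#' of mean 0 and variance `1/out_dim`. A `"left"` operator is
#' `out_dim x in_dim` and compresses samples; a `"right"` operator is
#' `in_dim x out_dim` and compresses markers. The operator is never stored
#' densely: any index range along the long axis regenerates identically for
#' a fixed seed (see [materialize_sketch()]), so streamed and one-shot
#' products agree exactly.
#'
#' The `"identity"` kind (requires `out_dim == in_dim`) is a documented test
#' mode that turns sketching off, used to compare the sketched pipeline
#' against exact unsketched computations.
#'
#' @param out_dim Sketch dimension `s`, `1 <= out_dim <= in_dim`.
#' @param in_dim Data dimension being compressed.
#' @param seed Integer seed; together with the entry index it fully
#'   determines every entry.
#' @param orientation `"left"` (sample sketch) or `"right"` (marker sketch).
#' @param kind `"gaussian"` or `"identity"`.
#' @return A `sketch_operator`.
#' @export
make_sketch <- function(out_dim, in_dim, seed = 1L,
                        orientation = c("left", "right"),
                        kind = c("gaussian", "identity")) {
  orientation <- match.arg(orientation)
  kind <- match.arg(kind)
  out_dim <- as.integer(out_dim)
  in_dim <- as.integer(in_dim)
  if (is.na(out_dim) || is.na(in_dim) || out_dim < 1L || in_dim < 1L) {
    stop("sketch dimensions must be positive integers")
  }
  if (out_dim > in_dim) {
    stop("sketch dimension exceeds data dimension (out_dim > in_dim)")
  }
  if (kind == "identity" && out_dim != in_dim) {
    stop("identity sketch requires out_dim == in_dim")
  }
  structure(
    list(kind = kind, out_dim = out_dim, in_dim = in_dim,
         seed = as.integer(seed), orientation = orientation),
    class = "sketch_operator"
  )
}

#' @export
print.sketch_operator <- function(x, ...) {
  cat(sprintf("sketch_operator: %s %s, %d x %d, seed %d\n",
              x$kind, x$orientation,
              if (x$orientation == "left") x$out_dim else x$in_dim,
              if (x$orientation == "left") x$in_dim else x$out_dim,
              x$seed))
  invisible(x)
}

#' Materialize part of a sketch operator
#'
#' Generates the dense entries for a set of indices along the operator's
#' long axis: columns of a `"left"` operator (one per sample), rows of a
#' `"right"` operator (one per marker). Deterministic in `(seed, index)` and
#' independent of the order or grouping of requests. The caller's RNG state
#' is left untouched.
#'
#' @param op A `sketch_operator`.
#' @param indices 1-based indices into the long axis (`in_dim`).
#' @return For `"left"`: an `out_dim x length(indices)` matrix; for
#'   `"right"`: a `length(indices) x out_dim` matrix.
#' @export
materialize_sketch <- function(op, indices = seq_len(op$in_dim)) {
  stopifnot(inherits(op, "sketch_operator"))
  indices <- as.integer(indices)
  if (length(indices) && (min(indices) < 1L || max(indices) > op$in_dim)) {
    stop("sketch indices out of range [1, in_dim]")
  }
  s <- op$out_dim
  if (op$kind == "identity") {
    M <- matrix(0, nrow = s, ncol = length(indices))
    M[cbind(indices, seq_along(indices))] <- 1
    return(if (op$orientation == "left") M else t(M))
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })

  salt <- if (op$orientation == "left") 1 else 2
  sd1s <- sqrt(1 / s)
  M <- matrix(0, nrow = s, ncol = length(indices))
  for (j in seq_along(indices)) {
    set.seed(.sketch_index_seed(op$seed, indices[j], salt))
    M[, j] <- stats::rnorm(s, mean = 0, sd = sd1s)
  }
  if (op$orientation == "left") M else t(M)
}

#' Sketch the samples of a genotype source
#'
#' Computes `Z_s1 = S1 Z`, the sample-sketched normalized genotype matrix,
#' streaming the normalized genotypes in marker blocks so the full `n x m`
#' matrix is never held in memory. Column order follows the retained BIM
#' order.
#'
#' @param source A `genotype_source`.
#' @param policy A [normalization_policy()].
#' @param S1 A `"left"` [make_sketch()] operator with `in_dim` equal to the
#'   number of streamed samples.
#' @param block_size Markers per streamed block.
#' @param samples Optional sample subset (indices into the source), e.g.
#'   after dropping missing phenotypes.
#' @return List with `Zs1` (`s1 x m_retained`), `variants` (retained rows of
#'   `source$variants`) and `variant_idx`.
#' @export
sketch_samples <- function(source, policy = normalization_policy(), S1,
                           block_size = 1024L, samples = NULL) {
  stopifnot(inherits(S1, "sketch_operator"))
  n_used <- if (is.null(samples)) source$n else length(samples)
  if (S1$orientation != "left" || S1$in_dim != n_used) {
    stop(sprintf("S1 must be a left sketch with in_dim = %d (got %s, in_dim = %d)",
                 n_used, S1$orientation, S1$in_dim))
  }
  S1full <- materialize_sketch(S1)
  it <- stream_blocks(source, policy, block_size = block_size,
                      samples = samples)
  parts <- list()
  vidx <- integer(0)
  while (!is.null(b <- it())) {
    parts[[length(parts) + 1L]] <- S1full %*% b$data
    vidx <- c(vidx, b$variant_idx)
  }
  if (length(parts) == 0L) {
    warning("no markers retained after filtering; sketched matrix is empty")
    Zs1 <- matrix(numeric(0), nrow = S1$out_dim, ncol = 0L)
  } else {
    Zs1 <- do.call(cbind, parts)
  }
  list(Zs1 = Zs1, variants = source$variants[vidx, , drop = FALSE],
       variant_idx = vidx)
}

#' Sketch the response vector
#'
#' Computes `y_s1 = S1 y` with the same sample-sketch operator used for the
#' genotypes.
#'
#' @param y Numeric vector of length `S1$in_dim` (no missing values).
#' @param S1 A `"left"` `sketch_operator`.
#' @return Numeric vector of length `S1$out_dim`.
#' @export
sketch_response <- function(y, S1) {
  stopifnot(inherits(S1, "sketch_operator"))
  if (S1$orientation != "left") stop("S1 must be a left (sample) sketch")
  if (length(y) != S1$in_dim) {
    stop(sprintf("response length %d does not match sketch in_dim %d",
                 length(y), S1$in_dim))
  }
  if (anyNA(y)) stop("response contains missing values")
  drop(materialize_sketch(S1) %*% y)
}

#' Sketched genetic relationship matrix
#'
#' Approximates the GRM of the normalized genotypes with both sample and
#' marker sketching: `K = S1 Z S2 S2' Z' S1'`, computed as
#' `B = sum over blocks of (S1 Z_b) S2[block rows, ]` followed by
#' `K = B B'`, so `K` is symmetric positive semidefinite by construction and
#' identical for any block partition. With both operators in identity mode
#' this is exactly `Z Z'`.
#'
#' @param source A `genotype_source` (ignored when `Zs1` is supplied).
#' @param policy A [normalization_policy()].
#' @param S1 Left (sample) `sketch_operator`.
#' @param S2 Right (marker) `sketch_operator` with `in_dim` equal to the
#'   retained marker count.
#' @param block_size Markers per streamed block.
#' @param samples Optional sample subset.
#' @param Zs1 Optional precomputed `s1 x m_retained` sample-sketched matrix
#'   (from [sketch_samples()]); avoids streaming the genotypes twice.
#' @return `s1 x s1` symmetric PSD matrix.
#' @export
sketched_grm <- function(source = NULL, policy = normalization_policy(),
                         S1, S2, block_size = 1024L, samples = NULL,
                         Zs1 = NULL) {
  stopifnot(inherits(S1, "sketch_operator"), inherits(S2, "sketch_operator"))
  if (S2$orientation != "right") stop("S2 must be a right (marker) sketch")
  s1 <- S1$out_dim
  s2 <- S2$out_dim
  B <- matrix(0, nrow = s1, ncol = s2)

  if (!is.null(Zs1)) {
    m <- ncol(Zs1)
    if (S2$in_dim != m) {
      stop(sprintf("S2 in_dim %d does not match retained marker count %d",
                   S2$in_dim, m))
    }
    lo <- 1L
    while (lo <= m) {
      hi <- min(lo + as.integer(block_size) - 1L, m)
      B <- B + Zs1[, lo:hi, drop = FALSE] %*% materialize_sketch(S2, lo:hi)
      lo <- hi + 1L
    }
  } else {
    S1full <- materialize_sketch(S1)
    it <- stream_blocks(source, policy, block_size = block_size,
                        samples = samples)
    total <- 0L
    while (!is.null(b <- it())) {
      rows <- (b$marker_range[1L] + 1L):b$marker_range[2L]
      B <- B + (S1full %*% b$data) %*% materialize_sketch(S2, rows)
      total <- b$marker_range[2L]
    }
    if (S2$in_dim != total) {
      stop(sprintf("S2 in_dim %d does not match retained marker count %d",
                   S2$in_dim, total))
    }
  }
  K <- tcrossprod(B)
  (K + t(K)) / 2
}
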