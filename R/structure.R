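# Population-structure covariates: principal components of the
# sample-sketched genotypes and assembly of the fixed-effect design matrix.

#' Top principal components of the sketched genotypes
#'
#' Computes PC scores of the sample-sketched matrix `Z_s1`: columns are
#' centered (the rows of `Z_s1` live in sketched-sample space and carry no
#' constant offset removal from the per-marker normalization), and the
#' scores are the top-`q` left singular vectors scaled by their singular
#' values, obtained from the eigendecomposition of the row Gram matrix.
#' Signs are fixed so the largest-magnitude loading of each score vector is
#' positive, making the result fully deterministic.
#'
#' @param Zs1 `s1 x m` numeric matrix.
#' @param q Number of components, `1 <= q < min(s1, m)`.
#' @param seed Unused by the exact decomposition; accepted for interface
#'   stability.
#' @return `s1 x q` score matrix with columns `PC1..PCq` and attribute
#'   `var_explained` (fraction of total variance per component).
#' @export
top_pcs <- function(Zs1, q, seed = NULL) {
  Zs1 <- as.matrix(Zs1)
  s1 <- nrow(Zs1)
  m <- ncol(Zs1)
  q <- as.integer(q)
  if (is.na(q) || q < 1L || q >= min(s1, m)) {
    stop(sprintf("`q` must satisfy 1 <= q < min(s1, m) = %d", min(s1, m)))
  }
  Xc <- scale(Zs1, center = TRUE, scale = FALSE)
  G <- tcrossprod(Xc)
  ee <- eigen((G + t(G)) / 2, symmetric = TRUE)
  ev <- pmax(ee$values, 0)
  total <- sum(ev)
  if (total <= 0) stop("sketched matrix has zero variance; no PCs defined")
  rel <- ev[seq_len(q)] / ev[1L]
  if (any(rel < 1e-12)) {
    warning(sprintf(
      "requested %d PCs but numerical rank is ~%d; trailing scores have zero variance",
      q, sum(ev / ev[1L] >= 1e-12)))
  }
  scores <- ee$vectors[, seq_len(q), drop = FALSE] *
    rep(sqrt(ev[seq_len(q)]), each = s1)
  # deterministic sign: largest-|.| element of each score positive
  for (j in seq_len(q)) {
    v <- scores[, j]
    i <- which.max(abs(v))
    if (length(i) && v[i] < 0) scores[, j] <- -v
  }
  colnames(scores) <- paste0("PC", seq_len(q))
  attr(scores, "var_explained") <- ev[seq_len(q)] / total
  scores
}

#' Assemble the covariate matrix in sketched-sample space
#'
#' Builds `X = [S1 1 | PCs | S1 C]`: the intercept column and any
#' user-supplied covariates `C` (given in original sample order) are pushed
#' through the same sample sketch as the genotypes and response, so all
#' columns live in the same `s1`-dimensional space as `y_s1`. The unsketched
#' model with an intercept maps to exactly the column `S1 1` under left
#' sketching, which is why a sketched intercept is included by default.
#'
#' @param pcs `s1 x q` PC score matrix from [top_pcs()], or `NULL`.
#' @param user_covars `n x c` numeric matrix in original sample order, or
#'   `NULL`.
#' @param S1 The `"left"` sketch operator used for the genotypes; required
#'   when an intercept or user covariates must be sketched.
#' @param include_intercept Include the sketched intercept column
#'   (default `TRUE`).
#' @return `s1 x k` matrix with column labels; errors if the result is
#'   column-rank deficient, naming the offending column.
#' @export
build_covariates <- function(pcs = NULL, user_covars = NULL, S1 = NULL,
                             include_intercept = TRUE) {
  cols <- list()
  labels <- character(0)
  s1 <- if (!is.null(pcs)) nrow(pcs) else if (!is.null(S1)) S1$out_dim else
    stop("need `pcs` or `S1` to determine the sketched dimension")

  if (include_intercept) {
    ones <- if (is.null(S1)) rep(1, s1) else
      drop(materialize_sketch(S1) %*% rep(1, S1$in_dim))
    cols[[length(cols) + 1L]] <- ones
    labels <- c(labels, "intercept")
  }
  if (!is.null(pcs)) {
    cols[[length(cols) + 1L]] <- as.matrix(pcs)
    labels <- c(labels, colnames(pcs) %||% paste0("PC", seq_len(ncol(pcs))))
  }
  if (!is.null(user_covars) && ncol(as.matrix(user_covars)) > 0L) {
    uc <- as.matrix(user_covars)
    if (is.null(S1)) stop("`S1` is required to sketch user covariates")
    if (nrow(uc) != S1$in_dim) {
      stop(sprintf("user covariates have %d rows but S1 in_dim is %d",
                   nrow(uc), S1$in_dim))
    }
    cols[[length(cols) + 1L]] <- materialize_sketch(S1) %*% uc
    labels <- c(labels, colnames(uc) %||% paste0("COV", seq_len(ncol(uc))))
  }
  if (length(cols) == 0L) {
    return(matrix(numeric(0), nrow = s1, ncol = 0L))
  }
  X <- do.call(cbind, cols)
  colnames(X) <- labels
  k <- ncol(X)
  if (k >= nrow(X)) {
    stop(sprintf("covariate count k = %d must be smaller than s1 = %d",
                 k, nrow(X)))
  }
  # rank check: name the first column linearly dependent on its predecessors
  qrX <- qr(X)
  if (qrX$rank < k) {
    dep <- setdiff(seq_len(k), sort(qrX$pivot[seq_len(qrX$rank)]))[1L]
    stop("collinear covariate column: ", labels[dep])
  }
  sv <- svd(X, nu = 0, nv = 0)$d
  if (sv[length(sv)] <= 1e-10 * sv[1L]) {
    stop("covariate matrix is numerically rank deficient")
  }
  X
}

`%||%` <- function(a, b) if (is.null(a)) b else a
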