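# Per-marker chi-squared association scan against the fitted sketched LMM.

#' Apply the inverse phenotypic covariance
#'
#' Returns the linear operator `x -> V^-1 x` where
#' `V = sigma_g2 (K/m + tau I)`, evaluated through the GRM spectrum:
#' `V^-1 x = U diag(1 / (sigma_g2 (lambda_i/m + tau))) U' x`.
#'
#' @param vc A `variance_components` fit with `sigma_g2 > 0`.
#' @param spectrum The [eigendecompose()] result used for the fit.
#' @return A function mapping an `s1`-vector (or `s1 x p` matrix) to
#'   `V^-1 x`; symmetric and linear.
#' @export
v_inverse_apply <- function(vc, spectrum) {
  stopifnot(inherits(vc, "variance_components"),
            inherits(spectrum, "grm_spectrum"))
  if (vc$sigma_g2 <= 0) {
    stop("sigma_g2 = 0: the genetic variance vanished; fall back to the ",
         "null model V = sigma_e2 * I")
  }
  U <- spectrum$vectors
  w <- 1 / (vc$sigma_g2 * (spectrum$values / spectrum$markers + vc$tau))
  function(x) {
    x <- as.matrix(x)
    U %*% (w * crossprod(U, x))
  }
}

#' Per-marker chi-squared association scan
#'
#' Computes, for every retained marker column `z` of the sample-sketched
#' genotypes, the score statistic
#' `chi^2 = (z~' V^-1 y~)^2 / (z~' V^-1 z~)`, where `y~` and `z~` are the
#' residuals of the sketched response and of the tested column after
#' generalized-least-squares projection on the covariates `X` under the
#' `V^-1` inner product. This is the standard GLS score test; with `X`
#' empty it reduces to the plain ratio. P-values are upper-tail
#' chi-squared with 1 degree of freedom. Markers whose residual norm
#' `z~' V^-1 z~` falls below `1e-12` are reported with `chisq = 0`,
#' `p = 1` and `degenerate = TRUE`.
#'
#' @param Zs1 `s1 x m` sample-sketched genotype matrix.
#' @param ys1 Sketched response (length `s1`).
#' @param X Sketched covariate matrix (`s1 x k`, possibly `NULL`).
#' @param vc A `variance_components` fit.
#' @param spectrum The [eigendecompose()] result used for the fit.
#' @param variants Data frame of retained variant records (`m` rows,
#'   columns `chrom`, `id`, `cm`, `bp`, `a1`, `a2`).
#' @return An `assoc_result` data frame with the variant columns plus
#'   `chisq`, `p` and `degenerate`, in BIM order; run metadata (tau, h2,
#'   sigma_g2, s1, mode) is attached as attributes.
#' @export
assoc_scan <- function(Zs1, ys1, X = NULL, vc, spectrum, variants) {
  stopifnot(inherits(vc, "variance_components"),
            inherits(spectrum, "grm_spectrum"))
  Zs1 <- as.matrix(Zs1)
  s1 <- nrow(Zs1)
  m <- ncol(Zs1)
  if (length(ys1) != s1) stop("ys1 length does not match Zs1 rows")
  if (nrow(spectrum$vectors) != s1) stop("spectrum dimension does not match Zs1")
  if (!is.null(X) && nrow(as.matrix(X)) != s1) {
    stop("covariate rows do not match Zs1")
  }
  if (nrow(variants) != m) stop("variant table does not match marker count")
  if (vc$sigma_g2 <= 0) {
    stop("sigma_g2 = 0: cannot form V^-1; fit the null model instead")
  }

  U <- spectrum$vectors
  w <- 1 / (vc$sigma_g2 * (spectrum$values / spectrum$markers + vc$tau))
  yt <- drop(crossprod(U, ys1))
  Zt <- crossprod(U, Zs1)

  if (!is.null(X) && ncol(as.matrix(X)) > 0L) {
    Xt <- crossprod(U, as.matrix(X))
    A <- crossprod(Xt, w * Xt)
    ry <- yt - drop(Xt %*% solve(A, crossprod(Xt, w * yt)))
    Rz <- Zt - Xt %*% solve(A, crossprod(Xt, w * Zt))
  } else {
    ry <- yt
    Rz <- Zt
  }

  num <- drop(crossprod(Rz, w * ry))
  den <- colSums(Rz * (w * Rz))
  degenerate <- den < 1e-12
  chisq <- numeric(m)
  ok <- !degenerate
  chisq[ok] <- num[ok]^2 / den[ok]
  p <- rep(1, m)
  p[ok] <- stats::pchisq(chisq[ok], df = 1L, lower.tail = FALSE)

  res <- data.frame(variants[, c("chrom", "id", "cm", "bp", "a1", "a2")],
                    chisq = chisq, p = p, degenerate = degenerate,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "tau") <- vc$tau
  attr(res, "h2") <- vc$h2
  attr(res, "sigma_g2") <- vc$sigma_g2
  attr(res, "s1") <- s1
  attr(res, "mode") <- vc$mode
  class(res) <- c("assoc_result", class(res))
  res
}

#' Write association summary statistics
#'
#' Writes a tab-separated summary file with columns
#' `CHR SNP BP A1 A2 CHISQ P`, one row per tested marker, p-values in
#' scientific notation with 6 significant digits after the point.
#'
#' @param results An `assoc_result` from [assoc_scan()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_assoc <- function(results, path) {
  if (is.null(results) || nrow(results) == 0L) {
    stop("empty association results")
  }
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open output path for writing: ", path)
  })
  on.exit(close(con))
  writeLines("CHR\tSNP\tBP\tA1\tA2\tCHISQ\tP", con)
  lines <- sprintf("%s\t%s\t%d\t%s\t%s\t%.8g\t%.6e",
                   results$chrom, results$id, results$bp,
                   results$a1, results$a2, results$chisq, results$p)
  writeLines(lines, con)
  invisible(path)
}
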