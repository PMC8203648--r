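# Voxel-wise GLM against the HRF design, statistical parametric maps and
# per-subject FDR thresholding.

#' Voxel-wise ordinary least squares GLM
#'
#' Fits every voxel's time course against the design matrix by OLS and
#' returns per-voxel, per-predictor betas, t statistics and two-sided p
#' values (each stimulus predictor tested against zero), plus residual
#' variance. Voxels with zero residual variance get `NA` t and p and are
#' flagged.
#'
#' @param series a [volume_series()] with `t` volumes.
#' @param design design matrix from [design_matrix()] with `t` rows and
#'   full column rank.
#' @return Object of class `glm_result`: list with `beta`, `t`, `p`
#'   (voxel x predictor matrices), `sigma2`, `df`, `dims` (spatial dims),
#'   `stimulus_columns`, `degenerate` (logical vector of flagged voxels).
#' @export
fit_glm <- function(series, design) {
  stopifnot(inherits(series, "volume_series"), is.matrix(design))
  d <- dim(series$data)
  nt <- d[4]
  if (nrow(design) != nt)
    stop("design has ", nrow(design), " rows but the series has ", nt, " volumes")
  qx <- qr(design)
  if (qx$rank < ncol(design)) {
    bad <- colnames(design)[qx$pivot[seq(qx$rank + 1L, ncol(design))]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  Y <- t(matrix(series$data, ncol = nt))            # t by voxels
  beta <- qr.coef(qx, Y)                            # p by voxels
  res <- qr.resid(qx, Y)
  df <- nt - ncol(design)
  sigma2 <- colSums(res^2) / df
  xtx_inv_diag <- diag(chol2inv(chol(crossprod(design))))
  se <- sqrt(outer(xtx_inv_diag, sigma2))
  tval <- beta / se
  degenerate <- sigma2 <= 0 | !is.finite(sigma2)
  tval[, degenerate] <- NA_real_
  pval <- 2 * stats::pt(-abs(tval), df)
  rn <- colnames(design)
  structure(list(beta = t(beta), t = t(tval), p = t(pval),
                 sigma2 = sigma2, df = df, dims = d[1:3],
                 predictors = rn,
                 stimulus_columns = attr(design, "stimulus_columns"),
                 degenerate = degenerate),
            class = "glm_result")
}

#' @export
print.glm_result <- function(x, ...) {
  cat(sprintf("<glm_result> %d voxels, predictors: %s (df = %d)\n",
              nrow(x$beta), paste(x$predictors, collapse = ", "), x$df))
  invisible(x)
}

#' Benjamini-Hochberg FDR threshold
#'
#' Step-up false-discovery-rate control at level `q` over a vector of p
#' values (one subject / one predictor): the largest `k` with
#' `p_(k) <= k q / m` determines the rejection threshold.
#'
#' @param pvalues numeric vector of p values (`NA` entries are never
#'   rejected and do not count toward `m`).
#' @param q FDR level in (0, 1).
#' @return Logical vector: `TRUE` where the hypothesis is rejected.
#' @examples
#' fdr_threshold(c(0.001, 0.002, 0.9, 0.95), q = 0.05)
#' @export
fdr_threshold <- function(pvalues, q = 0.05) {
  stopifnot(q > 0, q < 1)
  if (!length(pvalues)) return(logical(0))
  mask <- rep(FALSE, length(pvalues))
  ok <- !is.na(pvalues)
  if (any(ok))
    mask[ok] <- stats::p.adjust(pvalues[ok], method = "BH") <= q
  mask
}

#' Per-predictor activation mask
#'
#' Applies subject-level FDR control to one stimulus predictor's voxel-wise
#' p values, within an optional brain mask, and returns the significant
#' voxels as a 3D logical array. The sign of the effect is retained in the
#' returned attribute `sign`.
#'
#' @param glm a [fit_glm()] result.
#' @param predictor predictor name (one of `glm$stimulus_columns`).
#' @param q FDR level.
#' @param brain_mask optional 3D logical array restricting the tested
#'   voxels (defaults to all voxels).
#' @return Object of class `activation_mask`: 3D logical array with
#'   attributes `predictor`, `q` and `sign` (3D array of -1/0/+1).
#' @export
activation_mask <- function(glm, predictor, q = 0.05, brain_mask = NULL) {
  stopifnot(inherits(glm, "glm_result"))
  if (!predictor %in% glm$predictors) stop("unknown predictor: ", predictor)
  j <- match(predictor, glm$predictors)
  p <- glm$p[, j]
  if (is.null(brain_mask)) brain_mask <- array(TRUE, glm$dims)
  stopifnot(identical(dim(brain_mask), as.integer(glm$dims)) ||
              identical(dim(brain_mask), glm$dims))
  inb <- as.logical(brain_mask)
  sel <- rep(FALSE, length(p))
  sel[inb] <- fdr_threshold(p[inb], q)
  mask <- array(sel, glm$dims)
  sgn <- array(0, glm$dims)
  sgn[mask] <- sign(glm$beta[as.logical(mask), j])
  structure(mask, class = "activation_mask", predictor = predictor, q = q,
            sign = sgn)
}

#' Write a GLM statistic map or activation mask as NIfTI
#'
#' @param x a 3D array (e.g. a beta/t/p map reshaped to the grid) or an
#'   [activation_mask()].
#' @param path output NIfTI path.
#' @export
write_map_nifti <- function(x, path) {
  RNifti::writeNifti(RNifti::asNifti(x + 0), path)
  invisible(path)
}
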