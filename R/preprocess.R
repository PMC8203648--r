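# Volume-series container and preprocessing: initial-volume discard,
# pairwise temporal resampling, in-plane spatial smoothing, high-pass
# temporal filtering. Data are assumed motion-free and pre-registered;
# motion correction and affine registration are identity pass-throughs
# (see register_identity).

#' 4D BOLD volume series
#'
#' @param data 4D numeric array (x, y, z, t) of signal intensity.
#' @param tr repetition time in seconds.
#' @param voxel_size voxel edge lengths in mm (length 3).
#' @return Object of class `volume_series`.
#' @export
volume_series <- function(data, tr, voxel_size = c(0.234, 0.234, 0.5)) {
  stopifnot(is.array(data), length(dim(data)) == 4L, dim(data)[4] >= 1,
            is.numeric(tr), tr > 0, length(voxel_size) == 3L)
  if (!all(is.finite(data))) stop("volume series contains non-finite values")
  structure(list(data = data, tr = tr, voxel_size = voxel_size),
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_series> %d x %d x %d voxels, %d volumes, TR %gs\n",
              d[1], d[2], d[3], d[4], x$tr))
  invisible(x)
}

#' Discard initial volumes
#'
#' Drops the first `n` volumes (e.g. to avoid MR saturation effects).
#' Event onsets in an accompanying paradigm must be re-referenced by
#' `n * tr`; [shift_paradigm()] does that bookkeeping.
#'
#' @param series a [volume_series()].
#' @param n number of leading volumes to drop (`n < t`).
#' @return A [volume_series()] with `t - n` volumes.
#' @export
discard_initial <- function(series, n = 2) {
  stopifnot(inherits(series, "volume_series"), n >= 0)
  nt <- dim(series$data)[4]
  if (n >= nt) stop("cannot discard ", n, " of ", nt, " volumes")
  if (n == 0) return(series)
  volume_series(series$data[, , , -(seq_len(n)), drop = FALSE],
                tr = series$tr, voxel_size = series$voxel_size)
}

#' Re-reference paradigm onsets after discarding volumes
#'
#' @param paradigm a [paradigm()].
#' @param n_discarded number of volumes removed from the start.
#' @return A [paradigm()] with onsets shifted earlier by
#'   `n_discarded * tr` and `n_volumes` reduced accordingly.
#' @export
shift_paradigm <- function(paradigm, n_discarded) {
  ev <- paradigm$events
  ev$onset <- ev$onset - n_discarded * paradigm$tr
  if (nrow(ev) && any(ev$onset < 0))
    stop("discarding ", n_discarded, " volumes would move an event before scan start")
  paradigm(ev, tr = paradigm$tr, n_volumes = paradigm$n_volumes - n_discarded)
}

#' Pairwise volume averaging
#'
#' Resamples the series by averaging every two consecutive volumes,
#' doubling the repetition time (TR 2000 ms -> TR_eff 4000 ms). An odd
#' trailing volume is dropped.
#'
#' @param series a [volume_series()] with at least 2 volumes.
#' @return A [volume_series()] with `floor(t / 2)` volumes and `tr' = 2 tr`.
#' @export
pairwise_average <- function(series) {
  stopifnot(inherits(series, "volume_series"))
  nt <- dim(series$data)[4]
  if (nt < 2) stop("pairwise averaging needs at least 2 volumes")
  np <- nt %/% 2
  a <- series$data[, , , 2 * seq_len(np) - 1, drop = FALSE]
  b <- series$data[, , , 2 * seq_len(np), drop = FALSE]
  volume_series((a + b) / 2, tr = 2 * series$tr, voxel_size = series$voxel_size)
}

# 1D Gaussian convolution matrix with reflective boundary; rows sum to 1 so
# constants are preserved and in-plane mass is conserved.
.gauss_conv_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, ceiling(3 * sigma))
  w <- exp(-((-r):r)^2 / (2 * sigma^2))
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + ((-r):r)
    # half-sample reflection at the edges keeps the operator symmetric and
    # doubly stochastic: constants and total mass are both preserved
    j <- ifelse(j < 1L, 1L - j, j)
    j <- ifelse(j > n, 2L * n + 1L - j, j)
    j <- pmin(pmax(j, 1L), n)
    for (k in seq_along(j)) K[i, j[k]] <- K[i, j[k]] + w[k]
  }
  K
}

#' In-plane spatial smoothing
#'
#' Per-volume, per-slice 2D Gaussian smoothing with reflective boundary.
#' The kernel is specified by its full width at half maximum in voxels
#' (`sigma = fwhm / (2 sqrt(2 log 2))`).
#'
#' @param series a [volume_series()].
#' @param fwhm_vox kernel FWHM in voxels (in-plane); the default of 2
#'   voxels matches a 2-pixel kernel on a 64 x 64 matrix.
#' @return Smoothed [volume_series()].
#' @export
spatial_smooth <- function(series, fwhm_vox = 2) {
  stopifnot(inherits(series, "volume_series"), fwhm_vox > 0)
  sigma <- fwhm_vox / (2 * sqrt(2 * log(2)))
  d <- dim(series$data)
  Kx <- .gauss_conv_matrix(d[1], sigma)
  Ky <- .gauss_conv_matrix(d[2], sigma)
  out <- series$data
  arr <- series$data
  # separable convolution: one BLAS call per axis per slice, all volumes at once
  for (z in seq_len(d[3])) {
    sl <- arr[, , z, , drop = FALSE]          # x, y, 1, t
    m <- matrix(sl, nrow = d[1])              # x by (y * t)
    m <- Kx %*% m
    a2 <- array(m, c(d[1], d[2], d[4]))
    a2 <- aperm(a2, c(2, 1, 3))               # y, x, t
    m2 <- Ky %*% matrix(a2, nrow = d[2])
    a3 <- aperm(array(m2, c(d[2], d[1], d[4])), c(2, 1, 3))
    out[, , z, ] <- a3
  }
  volume_series(out, tr = series$tr, voxel_size = series$voxel_size)
}

# Projection basis for the temporal high-pass: constant, linear trend and
# the n_cycles lowest sine/cosine pairs (integer cycles per record).
.highpass_basis <- function(nt, n_cycles) {
  tt <- seq_len(nt)
  B <- cbind(1, tt - mean(tt))
  if (n_cycles >= 1) {
    for (k in seq_len(n_cycles)) {
      ang <- 2 * pi * k * (tt - 1) / nt
      B <- cbind(B, sin(ang), cos(ang))
    }
  }
  B
}

#' Temporal high-pass filtering with Gaussian smoothing
#'
#' Removes, per voxel, the linear trend and the `n_cycles` lowest-frequency
#' Fourier components (integer cycles per record), applies temporal Gaussian
#' smoothing of `smooth_fwhm_s` seconds FWHM, and re-projects out the same
#' basis so the output is exactly orthogonal to the removed components.
#'
#' @param series a [volume_series()].
#' @param n_cycles number of lowest Fourier cycles removed (default 9).
#' @param smooth_fwhm_s temporal smoothing FWHM in seconds (default 12);
#'   set to 0 to disable.
#' @return Filtered [volume_series()] (zero-mean per voxel).
#' @export
temporal_filter <- function(series, n_cycles = 9, smooth_fwhm_s = 12) {
  stopifnot(inherits(series, "volume_series"), n_cycles >= 0)
  d <- dim(series$data)
  nt <- d[4]
  if (nt < 2 * (n_cycles + 2)) stop("series too short for ", n_cycles, " cycles")
  Y <- t(matrix(series$data, ncol = nt))        # t by voxels
  Y <- .temporal_filter_matrix(Y, series$tr, n_cycles, smooth_fwhm_s)
  volume_series(array(t(Y), d), tr = series$tr, voxel_size = series$voxel_size)
}

# Operator cache: the basis QR and smoothing matrix depend only on
# (nt, n_cycles) and (nt, sigma); reuse them across subjects of a cohort.
.filter_cache <- new.env(parent = emptyenv())

# Core filter on a t-by-series matrix; shared with region-level filtering.
.temporal_filter_matrix <- function(Y, tr, n_cycles, smooth_fwhm_s) {
  nt <- nrow(Y)
  bkey <- sprintf("B_%d_%d", nt, n_cycles)
  if (is.null(.filter_cache[[bkey]]))
    .filter_cache[[bkey]] <- qr(.highpass_basis(nt, n_cycles))
  qb <- .filter_cache[[bkey]]
  Y <- qr.resid(qb, Y)
  if (smooth_fwhm_s > 0) {
    sigma <- smooth_fwhm_s / (2 * sqrt(2 * log(2))) / tr
    kkey <- sprintf("K_%d_%g", nt, sigma)
    if (is.null(.filter_cache[[kkey]]))
      .filter_cache[[kkey]] <- .gauss_conv_matrix(nt, sigma)
    Y <- .filter_cache[[kkey]] %*% Y
    Y <- qr.resid(qb, Y)   # smoothing may leak into the removed basis
  }
  Y
}

#' Identity registration placeholder
#'
#' Synthetic cohorts are generated pre-registered and motion-free, so
#' motion correction and affine registration to a reference anatomy reduce
#' to the identity. The function exists so externally registered data slot
#' into the same pipeline position.
#'
#' @param series a [volume_series()].
#' @return `series`, unchanged.
#' @export
register_identity <- function(series) {
  stopifnot(inherits(series, "volume_series"))
  series
}

#' Read / write a volume series as NIfTI
#'
#' @param series a [volume_series()].
#' @param path NIfTI file path (`.nii` / `.nii.gz`).
#' @rdname series_nifti
#' @export
write_series_nifti <- function(series, path) {
  img <- RNifti::asNifti(series$data)
  RNifti::pixdim(img) <- c(series$voxel_size, series$tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname series_nifti
#' @export
read_series_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  arr <- array(as.numeric(img), dim(img))
  volume_series(arr, tr = if (length(pd) >= 4 && pd[4] > 0) pd[4] else 1,
                voxel_size = pd[1:3])
}
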