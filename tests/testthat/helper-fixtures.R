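# Shared fixtures and independent oracles, all built in code.

# Small volume series wrapping a t-by-voxel matrix on a trivial 1D-ish grid.
series_from_matrix <- function(Y, tr = 4) {
  # Y: t x v
  v <- ncol(Y)
  volume_series(array(t(Y), c(v, 1, 1, nrow(Y))), tr = tr)
}

flat_series <- function(series) t(matrix(series$data, ncol = dim(series$data)[4]))

tiny_atlas <- function(seed = 1) make_atlas(c(10, 10, 4), n_regions = 6, seed = seed)

tc_from_matrix <- function(mat, tr = 4, subject = "s1") {
  if (is.null(rownames(mat)))
    rownames(mat) <- sprintf("R%03d", seq_len(nrow(mat)))
  region_timecourses_obj(mat, tr = tr, subject = subject)
}

# Independent Benjamini-Hochberg oracle: try every observed p value as the
# rejection threshold and keep the largest one satisfying the step-up bound.
bh_oracle <- function(p, q) {
  m <- length(p)
  best <- -Inf
  for (cand in sort(p)) {
    k <- sum(p <= cand)
    if (cand <= k * q / m) best <- max(best, cand)
  }
  p <= best
}

# Full-sort oracle for dual-channel thresholding (ignores tie-break order,
# compares edge sets).
threshold_oracle <- function(m, n_pos, n_neg) {
  ut <- which(upper.tri(m), arr.ind = TRUE)
  r <- m[ut]
  ok <- !is.na(r)
  ut <- ut[ok, , drop = FALSE]; r <- r[ok]
  key <- function(idx) paste(rownames(m)[ut[idx, 1]], rownames(m)[ut[idx, 2]],
                             sep = "|")
  pos <- which(r > 0); neg <- which(r < 0)
  pos <- pos[order(-r[pos])][seq_len(min(n_pos, length(pos)))]
  neg <- neg[order(r[neg])][seq_len(min(n_neg, length(neg)))]
  list(pos = sort(key(pos)), neg = sort(key(neg)))
}

edge_keys <- function(df) sort(paste(pmin(df$a, df$b), pmax(df$a, df$b), sep = "|"))

# Direct single-event convolution oracle on a fine grid (independent of
# design_matrix internals: plain Riemann-sum convolution).
conv_oracle <- function(onset, ramp, plateau, tr, n_volumes, hrf = hrf_params(),
                        dt = 0.05) {
  tg <- seq(0, tr * n_volumes, by = dt)
  s <- pmin(pmax((tg - onset) / ramp, 0), 1)
  s[tg >= onset + ramp + plateau] <- 0
  h <- two_gamma_hrf(tg, hrf)
  x <- numeric(length(tg))
  for (i in seq_along(tg)) {
    j <- seq_len(i)
    x[i] <- sum(s[j] * h[i - j + 1]) * dt
  }
  x[round((seq_len(n_volumes) - 1) * tr / dt) + 1]
}
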