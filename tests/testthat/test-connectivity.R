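test_that("global-mean removal centers regions and absorbs shared signals", {
  set.seed(71)
  mat <- matrix(rnorm(5 * 50), 5, 50,
                dimnames = list(sprintf("R%03d", 1:5), NULL))
  out <- remove_global_mean(tc_from_matrix(mat))
  expect_lt(max(abs(colMeans(out$mat))), 1e-12)
  # two identical regions become exactly zero
  two <- tc_from_matrix(matrix(rep(rnorm(30), 2), 2, 30, byrow = TRUE))
  expect_true(all(remove_global_mean(two)$mat == 0))
  # adding a shared common signal leaves the output unchanged
  shared <- sin(seq_len(50))
  out2 <- remove_global_mean(tc_from_matrix(sweep(mat, 2, -shared)))
  expect_equal(out2$mat, out$mat, tolerance = 1e-12)
  expect_error(remove_global_mean(tc_from_matrix(mat[1, , drop = FALSE])),
               "at least 2")
})

test_that("FC matrices follow the textbook Pearson formula", {
  x <- rnorm(40)
  mat <- rbind(R001 = x, R002 = x, R003 = -x)
  r <- fc_matrix(tc_from_matrix(mat))
  expect_equal(r["R001", "R002"], 1)
  expect_equal(r["R001", "R003"], -1)
  expect_true(all(is.na(diag(r))))
  # 3-region toy against hand-computed covariances
  a <- c(1, 2, 3, 4); b <- c(2, 1, 4, 3); c3 <- c(4, 3, 2, 1)
  toy <- rbind(R001 = a, R002 = b, R003 = c3)
  r2 <- fc_matrix(tc_from_matrix(toy))
  manual <- function(u, v) {
    sum((u - mean(u)) * (v - mean(v))) /
      sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  }
  expect_equal(r2["R001", "R002"], manual(a, b), tolerance = 1e-12)
  expect_equal(r2["R001", "R003"], manual(a, c3), tolerance = 1e-12)
  expect_equal(r2["R002", "R003"], manual(b, c3), tolerance = 1e-12)
  expect_true(isSymmetric(r2))
  # constant region flagged, not zero-filled
  const <- rbind(R001 = rnorm(10), R002 = rep(1, 10))
  expect_warning(rc <- fc_matrix(tc_from_matrix(const)), "constant")
  expect_true(is.na(rc["R001", "R002"]))
})

test_that("Fisher-z pooling matches direct evaluation and is stable", {
  m <- matrix(c(NA, 0.5, 0.5, NA), 2, 2,
              dimnames = list(c("R001", "R002"), c("R001", "R002")))
  expect_equal(group_mean_fc(list(m)), m, tolerance = 1e-12)
  m0 <- m; m0[1, 2] <- m0[2, 1] <- 0
  expect_equal(group_mean_fc(list(m0, m0))["R001", "R002"], 0)
  m8 <- m; m8[1, 2] <- m8[2, 1] <- 0.8
  expect_equal(group_mean_fc(list(m, m8))["R001", "R002"],
               tanh((atanh(0.5) + atanh(0.8)) / 2), tolerance = 1e-12)
  # entries undefined in one subject are averaged over the defined subset
  mna <- m; mna[1, 2] <- mna[2, 1] <- NA
  expect_equal(group_mean_fc(list(m, mna))["R001", "R002"], 0.5,
               tolerance = 1e-12)
  expect_error(group_mean_fc(list()), "empty")
  # symmetry is preserved and the z -> r -> z round trip is the identity
  set.seed(81)
  rs <- runif(50, -0.999, 0.999)
  expect_equal(tanh(atanh(rs)), rs, tolerance = 1e-9)
  mats <- lapply(1:3, function(i) {
    z <- matrix(rnorm(16, sd = 0.4), 4, 4); z <- (z + t(z)) / 2
    r <- tanh(z); diag(r) <- NA
    dimnames(r) <- list(sprintf("R%03d", 1:4), sprintf("R%03d", 1:4)); r
  })
  expect_true(isSymmetric(group_mean_fc(mats)))
})

test_that("dual-channel thresholding matches the full-sort oracle", {
  set.seed(91)
  for (i in 1:20) {
    n <- sample(6:15, 1)
    z <- matrix(rnorm(n * n), n, n); z <- (z + t(z)) / 2
    r <- tanh(z); diag(r) <- NA
    dimnames(r) <- list(sprintf("R%03d", 1:n), sprintf("R%03d", 1:n))
    n_pos <- sample(1:12, 1); n_neg <- sample(1:12, 1)
    thr <- suppressWarnings(threshold_fc(r, n_pos = n_pos, n_neg = n_neg))
    oracle <- threshold_oracle(r, n_pos, n_neg)
    expect_identical(edge_keys(thr$pos), oracle$pos)
    expect_identical(edge_keys(thr$neg), oracle$neg)
  }
})

test_that("thresholding is invariant to monotone transforms within sign classes", {
  set.seed(92)
  n <- 10
  z <- matrix(rnorm(n * n), n, n); z <- (z + t(z)) / 2
  r <- tanh(z); diag(r) <- NA
  dimnames(r) <- list(sprintf("R%03d", 1:n), sprintf("R%03d", 1:n))
  thr <- threshold_fc(r, n_pos = 8, n_neg = 8)
  # odd monotone transform preserves sign and order
  thr2 <- threshold_fc(sign(r) * abs(r)^1.7, n_pos = 8, n_neg = 8)
  expect_identical(edge_keys(thr$pos), edge_keys(thr2$pos))
  expect_identical(edge_keys(thr$neg), edge_keys(thr2$neg))
})

test_that("thresholding handles degenerate channels and warns when short", {
  r <- matrix(-0.5, 4, 4); diag(r) <- NA
  dimnames(r) <- list(sprintf("R%03d", 1:4), sprintf("R%03d", 1:4))
  thr <- suppressWarnings(threshold_fc(r, n_pos = 3, n_neg = 3))
  expect_equal(nrow(thr$pos), 0)                    # all entries negative
  expect_warning(threshold_fc(r, n_pos = 0, n_neg = 100), "available")
  expect_error(threshold_fc(r, regions = c("R001", "nope")), "absent")
})

test_that("differential FC flags planted group differences with the right sign", {
  set.seed(101)
  n <- 6; nt <- 400
  rn <- sprintf("R%03d", 1:n)
  make_fc <- function(couple) {
    mat <- matrix(rnorm(n * nt), n, nt, dimnames = list(rn, NULL))
    if (couple) {
      shared <- rnorm(nt)
      mat[1, ] <- 0.5 * mat[1, ] + shared
      mat[2, ] <- 0.5 * mat[2, ] + shared
    }
    fc_matrix(tc_from_matrix(mat))
  }
  fc_ctrl <- lapply(1:5, function(i) make_fc(FALSE))
  fc_trt <- lapply(1:9, function(i) make_fc(TRUE))
  uni <- suppressWarnings(threshold_fc(group_mean_fc(fc_trt), n_pos = 3, n_neg = 3))
  d <- diff_fc(fc_ctrl, fc_trt, uni, alpha = 0.05)
  expect_equal(d$pos["R001", "R002"], 1)
  expect_true(all(d$pos %in% c(-1, 0, 1)))
  # identical groups: all indicators zero
  d0 <- diff_fc(fc_ctrl, fc_ctrl, uni, alpha = 0.05)
  expect_true(all(d0$pos == 0) && all(d0$neg == 0))
  # paired test demands equal sizes
  expect_error(diff_fc(fc_ctrl, fc_trt, uni, test = "paired"), "equal group sizes")
})

test_that("composite aggregation reproduces the signed-count worked example", {
  # two composite nodes; eight constituent connections between them:
  # seven greater in control (-1), one greater in treated (+1) -> net -6
  rn <- sprintf("R%03d", 1:8)
  pos <- matrix(0L, 8, 8, dimnames = list(rn, rn))
  pairs <- cbind(1:4, 5:8)                   # 4 pos-channel pairs, A x B
  neg <- pos
  for (i in 1:4) {
    pos[pairs[i, 1], pairs[i, 2]] <- pos[pairs[i, 2], pairs[i, 1]] <- -1L
    neg[pairs[i, 1], pairs[i, 2]] <- neg[pairs[i, 2], pairs[i, 1]] <-
      if (i == 1) 1L else -1L
  }
  d <- diff_fc_matrix(pos, neg)
  membership <- setNames(rep(c("A", "B"), each = 4), rn)
  net <- aggregate_composite(d, membership, display_threshold = 0)
  expect_equal(net$net["A", "B"], -6)
  expect_equal(net$edges$net_fc, -6)
  expect_equal(net$edges$pos_sum, -4)
  expect_equal(net$edges$neg_sum, -2)
})

test_that("composite aggregation validates membership and filters by threshold", {
  rn <- sprintf("R%03d", 1:6)
  pos <- matrix(0L, 6, 6, dimnames = list(rn, rn))
  pos[1, 4] <- pos[4, 1] <- 1L
  pos[2, 5] <- pos[5, 2] <- 1L
  d <- diff_fc_matrix(pos)
  mem <- setNames(rep(c("A", "B", "C"), each = 2), rn)
  # all-zero differential matrix: empty displayed network
  net0 <- aggregate_composite(diff_fc_matrix(pos * 0L), mem, 0)
  expect_equal(nrow(net0$edges), 0)
  # threshold monotonicity: higher display threshold shows a subset
  n0 <- aggregate_composite(d, mem, 0)
  n1 <- aggregate_composite(d, mem, 1)
  key <- function(n) paste(n$edges$from, n$edges$to)
  expect_true(all(key(n1) %in% key(n0)))
  # overlapping membership rejected; uncovered regions rejected
  expect_error(aggregate_composite(d, list(A = rn[1:3], B = rn[3:6])),
               "overlap")
  expect_error(aggregate_composite(d, mem[1:4]), "cover")
})

test_that("pseudo-directioning follows the structural prior edge by edge", {
  rn <- sprintf("R%03d", 1:6)
  pos <- matrix(0L, 6, 6, dimnames = list(rn, rn))
  pos[1, 3] <- pos[3, 1] <- 1L   # A-B
  pos[1, 5] <- pos[5, 1] <- 1L   # A-C
  pos[3, 5] <- pos[5, 3] <- 1L   # B-C
  d <- diff_fc_matrix(pos)
  mem <- setNames(rep(c("A", "B", "C"), each = 2), rn)
  net <- aggregate_composite(d, mem, 0)
  prior <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  prior["A", "B"] <- 1                      # A projects to B
  prior["B", "C"] <- 1; prior["C", "B"] <- 1  # reciprocal
  dir <- pseudo_direct(net, prior)
  e <- dir$edges
  get <- function(a, b) e[e$from == a & e$to == b, ]
  expect_identical(get("A", "B")$direction, "from->to")
  expect_identical(get("B", "C")$direction, "bidirectional")
  expect_identical(get("A", "C")$direction, "undirected")
  expect_true(get("A", "C")$no_prior)
  # empty prior: everything undirected
  e0 <- pseudo_direct(net, prior * 0)$edges
  expect_true(all(e0$direction == "undirected"))
  # random priors match a per-edge lookup oracle
  set.seed(111)
  for (i in 1:20) {
    pr <- matrix(rbinom(9, 1, 0.5), 3, 3,
                 dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
    ed <- pseudo_direct(net, pr)$edges
    for (j in seq_len(nrow(ed))) {
      a <- ed$from[j]; b <- ed$to[j]
      want <- if (pr[a, b] && pr[b, a]) "bidirectional"
        else if (pr[a, b] == 1) "from->to"
        else if (pr[b, a] == 1) "to->from"
        else "undirected"
      expect_identical(ed$direction[j], want)
    }
  }
})

test_that("condition comparison counts edge-set overlaps", {
  rn <- sprintf("R%03d", 1:10)
  mem <- setNames(rep(LETTERS[1:5], each = 2), rn)
  net_from_pairs <- function(pairs) {
    pos <- matrix(0L, 10, 10, dimnames = list(rn, rn))
    for (p in pairs) pos[p[1], p[2]] <- pos[p[2], p[1]] <- 1L
    aggregate_composite(diff_fc_matrix(pos), mem, 0)
  }
  # composite pairs: (A,B), (A,C), (B,C), (C,D), (D,E), (A,E) via region pairs
  n1 <- net_from_pairs(list(c(1, 3), c(1, 5), c(3, 5), c(5, 7), c(7, 9)))
  n2 <- net_from_pairs(list(c(2, 4), c(2, 6), c(4, 6), c(1, 9), c(3, 9), c(5, 9)))
  cmp <- compare_conditions(n1, n2)
  expect_equal(cmp$overlap, 3)   # A-B, A-C, B-C shared
  expect_equal(compare_conditions(n1, n1)$overlap, nrow(n1$edges))
  n3 <- net_from_pairs(list(c(2, 10)))
  expect_equal(compare_conditions(n1, n3)$overlap, 0)
  bad <- net_from_pairs(list(c(1, 3)))
  bad$net <- bad$net[1:2, 1:2]
  expect_error(compare_conditions(n1, bad), "node space")
})

test_that("FC matrices and networks round-trip through TSV and GraphML", {
  set.seed(121)
  r <- matrix(runif(16, -1, 1), 4, 4); r <- (r + t(r)) / 2; diag(r) <- NA
  dimnames(r) <- list(sprintf("R%03d", 1:4), sprintf("R%03d", 1:4))
  path <- tempfile(fileext = ".tsv")
  write_fc_tsv(r, path)
  expect_equal(read_fc_tsv(path), r, tolerance = 1e-12)
  rn <- sprintf("R%03d", 1:4)
  pos <- matrix(0L, 4, 4, dimnames = list(rn, rn))
  pos[1, 3] <- pos[3, 1] <- 1L
  net <- aggregate_composite(diff_fc_matrix(pos),
                             setNames(rep(c("A", "B"), each = 2), rn), 0)
  gpath <- tempfile(fileext = ".graphml")
  write_network_graphml(net, gpath)
  g <- igraph::read_graph(gpath, format = "graphml")
  expect_equal(igraph::gsize(g), 1)
  expect_setequal(igraph::V(g)$name, c("A", "B"))
})
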