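# Differential functional-connectivity procedure: global-mean removal,
# Pearson matrices, Fisher-z group pooling, fixed-edge-count dual-channel
# thresholding, per-edge t-tests, signed net-FC aggregation over composite
# nodes, pseudo-directioning by a structural prior, and cross-condition
# network comparison.

.FISHER_CLIP <- 1 - 1e-7

#' Remove the global mean signal
#'
#' Subtracts, at each timepoint, the mean across regions from every
#' region's time course. Any signal common to all regions (e.g. the
#' stimulus-evoked component shared brain-wide) is removed exactly.
#'
#' @param tc a [region_timecourses_obj()] with at least 2 regions.
#' @return A [region_timecourses_obj()] whose column means are zero.
#' @export
remove_global_mean <- function(tc) {
  stopifnot(inherits(tc, "region_timecourses"))
  if (nrow(tc$mat) < 2) stop("global mean removal needs at least 2 regions")
  out <- tc
  out$mat <- sweep(tc$mat, 2, colMeans(tc$mat))
  out
}

#' Pearson functional-connectivity matrix
#'
#' Pairwise Pearson correlation between full-length region time courses.
#' The diagonal is excluded (`NA`); entries involving a constant
#' (zero-variance) region are undefined and flagged with a warning, never
#' zero-filled.
#'
#' @param tc a [region_timecourses_obj()] (typically after
#'   [remove_global_mean()]) with at least 3 timepoints.
#' @return Symmetric region x region correlation matrix with `NA` diagonal.
#' @export
fc_matrix <- function(tc) {
  stopifnot(inherits(tc, "region_timecourses"))
  if (ncol(tc$mat) < 3) stop("correlation needs at least 3 timepoints")
  sds <- apply(tc$mat, 1, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  if (any(const))
    warning("constant region(s) with undefined correlations: ",
            paste(rownames(tc$mat)[const], collapse = ", "))
  r <- suppressWarnings(stats::cor(t(tc$mat)))
  r[const, ] <- NA_real_
  r[, const] <- NA_real_
  diag(r) <- NA_real_
  r
}

#' Fisher-z pooled group-mean FC matrix
#'
#' Converts each subject's correlations to Fisher z (`atanh`, after
#' clipping to +/-(1 - 1e-7)), averages entrywise over the subjects in
#' which the entry is defined, and converts back (`tanh`).
#'
#' @param matrices non-empty list of subject FC matrices sharing region
#'   order.
#' @return Group-mean FC matrix on the r scale.
#' @export
group_mean_fc <- function(matrices) {
  if (!length(matrices)) stop("empty list of FC matrices")
  rn <- rownames(matrices[[1]])
  for (m in matrices)
    if (!identical(rownames(m), rn))
      stop("FC matrices do not share region order")
  zs <- lapply(matrices, function(m) atanh(pmin(pmax(m, -.FISHER_CLIP), .FISHER_CLIP)))
  zsum <- Reduce(`+`, lapply(zs, function(z) ifelse(is.na(z), 0, z)))
  zn <- Reduce(`+`, lapply(zs, function(z) (!is.na(z)) + 0))
  out <- tanh(zsum / zn)
  out[zn == 0] <- NA_real_
  dimnames(out) <- dimnames(matrices[[1]])
  out
}

#' Dual-channel fixed-edge-count thresholding
#'
#' Restricts a group-mean FC matrix to the selected regions and keeps the
#' `n_pos` strongest positive correlations (pCorrs) and the `n_neg` lowest
#' negative correlations (nCorrs) among the unique region pairs. With 100
#' regions and 500 edges per channel the mean node degree is the commonly
#' used k = 10. Ties at the boundary break by (|r| descending, region index
#' pair ascending) for a stable edge set.
#'
#' @param mean_fc group-mean FC matrix (e.g. from [group_mean_fc()]).
#' @param regions character vector of selected region names (e.g. from
#'   [activation_probability()]); defaults to all.
#' @param n_pos,n_neg number of retained edges per channel (default 500).
#' @return Object of class `thresholded_fc`: list with `pos` and `neg`
#'   edge data frames (`a`, `b`, `r`), `regions`, and `k` (mean node degree
#'   per channel).
#' @export
threshold_fc <- function(mean_fc, regions = rownames(mean_fc),
                         n_pos = 500, n_neg = 500) {
  stopifnot(is.matrix(mean_fc), !is.null(rownames(mean_fc)))
  if (!all(regions %in% rownames(mean_fc)))
    stop("selected region(s) absent from the matrix: ",
         paste(setdiff(regions, rownames(mean_fc)), collapse = ", "))
  m <- mean_fc[regions, regions, drop = FALSE]
  n <- length(regions)
  ut <- which(upper.tri(m), arr.ind = TRUE)
  r <- m[ut]
  ok <- !is.na(r)
  ut <- ut[ok, , drop = FALSE]; r <- r[ok]
  pick <- function(idx, k, label) {
    if (length(idx) < k)
      warning("only ", length(idx), " ", label, " edges available; requested ", k)
    ord <- order(-abs(r[idx]), ut[idx, 1], ut[idx, 2])
    idx[ord][seq_len(min(k, length(idx)))]
  }
  ip <- pick(which(r > 0), n_pos, "positive")
  im <- pick(which(r < 0), n_neg, "negative")
  edge_df <- function(idx) data.frame(a = regions[ut[idx, 1]],
                                      b = regions[ut[idx, 2]],
                                      r = r[idx], stringsAsFactors = FALSE)
  structure(list(pos = edge_df(ip), neg = edge_df(im), regions = regions,
                 k = c(positive = 2 * length(ip) / n,
                       negative = 2 * length(im) / n)),
            class = "thresholded_fc")
}

#' @export
print.thresholded_fc <- function(x, ...) {
  cat(sprintf("<thresholded_fc> %d regions; %d pCorrs (k = %.1f), %d nCorrs (k = %.1f)\n",
              length(x$regions), nrow(x$pos), x$k["positive"],
              nrow(x$neg), x$k["negative"]))
  invisible(x)
}

# Union of edge sets over one or more thresholded_fc objects, per channel.
.edge_universe <- function(universe) {
  if (inherits(universe, "thresholded_fc")) universe <- list(universe)
  stopifnot(all(vapply(universe, inherits, logical(1), "thresholded_fc")))
  key <- function(df) paste(pmin(df$a, df$b), pmax(df$a, df$b), sep = "|")
  per_channel <- function(ch) {
    e <- do.call(rbind, lapply(universe, `[[`, ch))
    if (!nrow(e)) return(e[, c("a", "b")])
    e <- e[!duplicated(key(e)), c("a", "b"), drop = FALSE]
    rownames(e) <- NULL
    e
  }
  list(pos = per_channel("pos"), neg = per_channel("neg"),
       regions = sort(unique(unlist(lapply(universe, `[[`, "regions")))))
}

#' Per-edge differential FC tests
#'
#' For every edge of the universe (the union of the groups' thresholded
#' channels), a two-tailed Student's t test compares the two groups'
#' subject-level Fisher-z correlations. Edges with `p <= alpha`
#' (uncorrected) get a signed indicator: +1 where the treated group is
#' greater, -1 where the control group is greater, 0 otherwise.
#'
#' @param fc_control,fc_treated lists of subject FC matrices (or of
#'   [region_timecourses_obj()], which are then global-mean-removed and
#'   correlated), at least 2 subjects each.
#' @param universe a [threshold_fc()] result or list of them; the tested
#'   edge set is the per-channel union.
#' @param test `"homoscedastic"` (pooled-variance two-sample t) or
#'   `"paired"` (requires equal group sizes with subjects paired by
#'   position).
#' @param alpha per-edge significance level (default 0.05, uncorrected).
#' @return Object of class `diff_fc`: list with `pos` and `neg` indicator
#'   matrices (region x region, entries -1/0/+1), `edges` (per-edge test
#'   table), `regions`, `alpha`, `test`.
#' @export
diff_fc <- function(fc_control, fc_treated, universe,
                    test = c("homoscedastic", "paired"), alpha = 0.05) {
  test <- match.arg(test)
  as_fc <- function(x) {
    if (inherits(x, "region_timecourses")) fc_matrix(remove_global_mean(x))
    else x
  }
  fc_control <- lapply(fc_control, as_fc)
  fc_treated <- lapply(fc_treated, as_fc)
  if (length(fc_control) < 2 || length(fc_treated) < 2)
    stop("each group needs at least 2 subjects")
  if (test == "paired" && length(fc_control) != length(fc_treated))
    stop("paired test requires equal group sizes with matched ordering")
  uni <- .edge_universe(universe)
  regions <- uni$regions
  zval <- function(mats, a, b)
    vapply(mats, function(m) {
      if (!(a %in% rownames(m)) || !(b %in% rownames(m))) return(NA_real_)
      atanh(min(max(m[a, b], -.FISHER_CLIP), .FISHER_CLIP))
    }, numeric(1))
  ind <- function(ch) {
    M <- matrix(0L, length(regions), length(regions),
                dimnames = list(regions, regions))
    ed <- uni[[ch]]
    rows <- NULL
    for (i in seq_len(nrow(ed))) {
      a <- ed$a[i]; b <- ed$b[i]
      zc <- zval(fc_control, a, b); zt <- zval(fc_treated, a, b)
      if (test == "paired") {
        ok <- !is.na(zc) & !is.na(zt)
        zc <- zc[ok]; zt <- zt[ok]
        if (length(zc) < 2) next
        ht <- stats::t.test(zt, zc, paired = TRUE)
      } else {
        zc <- zc[!is.na(zc)]; zt <- zt[!is.na(zt)]
        if (length(zc) < 2 || length(zt) < 2) next
        ht <- stats::t.test(zt, zc, var.equal = TRUE)
      }
      sig <- !is.na(ht$p.value) && ht$p.value <= alpha
      s <- if (sig) as.integer(sign(mean(zt) - mean(zc))) else 0L
      M[a, b] <- M[b, a] <- s
      rows <- rbind(rows, data.frame(a = a, b = b, channel = ch,
                                     mean_z_control = mean(zc),
                                     mean_z_treated = mean(zt),
                                     p = ht$p.value, indicator = s,
                                     stringsAsFactors = FALSE))
    }
    list(M = M, rows = rows)
  }
  rp <- ind("pos"); rn <- ind("neg")
  structure(list(pos = rp$M, neg = rn$M,
                 edges = rbind(rp$rows, rn$rows),
                 regions = regions, alpha = alpha, test = test),
            class = "diff_fc")
}

#' Construct a differential FC matrix from indicator matrices
#'
#' Builds the `diff_fc` container directly from signed indicator matrices,
#' e.g. to aggregate externally computed edge tests or to construct worked
#' examples. Entries must be -1 (control greater), 0 (not significant) or
#' +1 (treated greater).
#'
#' @param pos,neg symmetric region x region indicator matrices (shared
#'   dimnames); either may be omitted (treated as all-zero).
#' @param alpha,test recorded test metadata.
#' @return A `diff_fc` object as returned by [diff_fc()].
#' @export
diff_fc_matrix <- function(pos, neg = NULL, alpha = 0.05,
                           test = "homoscedastic") {
  if (is.null(neg)) neg <- array(0L, dim(pos), dimnames = dimnames(pos))
  if (is.null(pos)) pos <- array(0L, dim(neg), dimnames = dimnames(neg))
  stopifnot(is.matrix(pos), is.matrix(neg), identical(dim(pos), dim(neg)),
            !is.null(rownames(pos)),
            all(pos %in% c(-1L, 0L, 1L)), all(neg %in% c(-1L, 0L, 1L)),
            isSymmetric(unname(pos)), isSymmetric(unname(neg)))
  structure(list(pos = pos, neg = neg, edges = NULL,
                 regions = rownames(pos), alpha = alpha, test = test),
            class = "diff_fc")
}

#' Aggregate differential FC into a composite-node network
#'
#' Sums the signed per-edge indicators (both correlation channels) over all
#' constituent region pairs between two composite nodes, giving the net FC
#' of that composite edge: a net FC of -6 means six more significant
#' connections were greater in the control group than in the treated group
#' (e.g. seven control-greater and one treated-greater). Edges with
#' `|net| <= display_threshold` are suppressed from the displayed edge list
#' but kept in the full matrix; within-composite sums appear on the
#' diagonal and are never displayed as edges.
#'
#' @param diff a [diff_fc()] result.
#' @param membership region -> composite map: either a named character
#'   vector (names = regions) or a named list of non-overlapping region
#'   vectors (names = composites). Must cover all regions in `diff`.
#' @param display_threshold display cut: only edges with
#'   `|net| > display_threshold` are listed (e.g. 4 for laser-only, 6 for
#'   nociception contrasts).
#' @return Object of class `composite_network`: list with `net` (composite
#'   x composite signed-count matrix), `edges` (displayed edge data frame:
#'   from, to, net_fc, pos_sum, neg_sum, direction), `display_threshold`,
#'   `membership`.
#' @export
aggregate_composite <- function(diff, membership, display_threshold = 0) {
  stopifnot(inherits(diff, "diff_fc"), display_threshold >= 0)
  if (is.list(membership) && !is.null(names(membership))) {
    regs <- unlist(membership, use.names = FALSE)
    if (anyDuplicated(regs))
      stop("overlapping composite membership: ",
           paste(unique(regs[duplicated(regs)]), collapse = ", "))
    membership <- stats::setNames(rep(names(membership), lengths(membership)), regs)
  }
  if (!all(diff$regions %in% names(membership)))
    stop("membership does not cover region(s): ",
         paste(setdiff(diff$regions, names(membership)), collapse = ", "))
  comp_of <- membership[diff$regions]
  comps <- sort(unique(unname(comp_of)))
  net <- pos_sum <- neg_sum <-
    matrix(0L, length(comps), length(comps), dimnames = list(comps, comps))
  n <- length(diff$regions)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    ci <- comp_of[[i]]; cj <- comp_of[[j]]
    p <- diff$pos[i, j]; q <- diff$neg[i, j]
    if (p == 0 && q == 0) next
    pos_sum[ci, cj] <- pos_sum[ci, cj] + p
    neg_sum[ci, cj] <- neg_sum[ci, cj] + q
    if (ci != cj) {
      pos_sum[cj, ci] <- pos_sum[ci, cj]
      neg_sum[cj, ci] <- neg_sum[ci, cj]
    }
  }
  net <- pos_sum + neg_sum
  edges <- NULL
  if (length(comps) > 1) {
    for (i in seq_len(length(comps) - 1)) for (j in seq(i + 1, length(comps))) {
      if (abs(net[i, j]) > display_threshold) {
        edges <- rbind(edges, data.frame(
          from = comps[i], to = comps[j], net_fc = net[i, j],
          pos_sum = pos_sum[i, j], neg_sum = neg_sum[i, j],
          direction = "undirected", stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(edges))
    edges <- data.frame(from = character(), to = character(),
                        net_fc = integer(), pos_sum = integer(),
                        neg_sum = integer(), direction = character())
  structure(list(net = net, edges = edges,
                 display_threshold = display_threshold,
                 membership = membership),
            class = "composite_network")
}

#' @export
print.composite_network <- function(x, ...) {
  cat(sprintf("<composite_network> %d composite nodes, %d displayed edges (|net| > %g)\n",
              nrow(x$net), nrow(x$edges), x$display_threshold))
  if (nrow(x$edges)) print(x$edges)
  invisible(x)
}

#' Pseudo-direction FC changes with a structural prior
#'
#' Functional connectivity is undirected; a directed structural
#' connectivity prior (anterograde projections, "synapses" forming on the
#' target region) assigns each displayed edge a direction: A -> B where the
#' prior has a projection A -> B only, bidirectional where both exist, and
#' undirected (flagged) where the prior is silent.
#'
#' @param network a [aggregate_composite()] result.
#' @param prior square numeric matrix indexed by composite node names;
#'   `prior[A, B] != 0` means a structural projection from A to B.
#' @return The network with `edges$direction` set to `"from->to"`,
#'   `"to->from"`, `"bidirectional"` or `"undirected"`, and a logical
#'   column `no_prior` flagging edges the prior does not cover.
#' @export
pseudo_direct <- function(network, prior) {
  stopifnot(inherits(network, "composite_network"), is.matrix(prior),
            !is.null(rownames(prior)))
  e <- network$edges
  e$no_prior <- FALSE
  for (i in seq_len(nrow(e))) {
    a <- e$from[i]; b <- e$to[i]
    fab <- a %in% rownames(prior) && b %in% colnames(prior) && prior[a, b] != 0
    fba <- b %in% rownames(prior) && a %in% colnames(prior) && prior[b, a] != 0
    e$direction[i] <- if (fab && fba) "bidirectional"
      else if (fab) "from->to"
      else if (fba) "to->from"
      else "undirected"
    e$no_prior[i] <- !fab && !fba
  }
  network$edges <- e
  network
}

#' Compare two displayed composite networks
#'
#' Counts the overlap of the displayed edge sets of two networks sharing a
#' node space and, where group-mean FC matrices are supplied, compares the
#' mean absolute Fisher-z strength over each shared composite edge's
#' constituent region pairs.
#'
#' @param net_a,net_b [aggregate_composite()] results over the same
#'   composite node space.
#' @param fc_a,fc_b optional region-level group-mean FC matrices used for
#'   the strength comparison.
#' @return List with `overlap` (count), `shared` (data frame of shared
#'   edges, with `strength_a`, `strength_b` and `stronger` when FC matrices
#'   are given), and the two networks' displayed edge counts.
#' @export
compare_conditions <- function(net_a, net_b, fc_a = NULL, fc_b = NULL) {
  stopifnot(inherits(net_a, "composite_network"),
            inherits(net_b, "composite_network"))
  if (!identical(sort(rownames(net_a$net)), sort(rownames(net_b$net))))
    stop("networks do not share a composite node space")
  key <- function(e) paste(pmin(e$from, e$to), pmax(e$from, e$to), sep = "|")
  ka <- key(net_a$edges); kb <- key(net_b$edges)
  shared_keys <- intersect(ka, kb)
  shared <- net_a$edges[ka %in% shared_keys, c("from", "to"), drop = FALSE]
  rownames(shared) <- NULL
  if (!is.null(fc_a) && !is.null(fc_b) && nrow(shared)) {
    strength <- function(fc, from, to, membership) {
      ra <- names(membership)[membership == from]
      rb <- names(membership)[membership == to]
      ra <- intersect(ra, rownames(fc)); rb <- intersect(rb, rownames(fc))
      z <- abs(atanh(pmin(pmax(fc[ra, rb, drop = FALSE], -.FISHER_CLIP),
                          .FISHER_CLIP)))
      mean(z, na.rm = TRUE)
    }
    shared$strength_a <- mapply(strength, shared$from, shared$to,
                                MoreArgs = list(fc = fc_a,
                                                membership = net_a$membership))
    shared$strength_b <- mapply(strength, shared$from, shared$to,
                                MoreArgs = list(fc = fc_b,
                                                membership = net_b$membership))
    shared$stronger <- ifelse(shared$strength_a > shared$strength_b, "a", "b")
  }
  list(overlap = length(shared_keys), shared = shared,
       n_edges_a = nrow(net_a$edges), n_edges_b = nrow(net_b$edges))
}

#' FC matrix / network I/O
#'
#' `write_fc_tsv` and `read_fc_tsv` store square matrices as TSV with a
#' region header row and column. `write_network_graphml` exports a
#' composite network (with `net_fc` and `direction` edge attributes) as
#' GraphML; `read_structural_prior_tsv` reads a directed structural prior
#' as a square TSV.
#'
#' @param mat square matrix with dimnames.
#' @param path file path.
#' @rdname fc_io
#' @export
write_fc_tsv <- function(mat, path) {
  utils::write.table(mat, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname fc_io
#' @export
read_fc_tsv <- function(path) {
  as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
}

#' @rdname fc_io
#' @export
read_structural_prior_tsv <- function(path) read_fc_tsv(path)

#' @param network a [aggregate_composite()] result.
#' @rdname fc_io
#' @export
write_network_graphml <- function(network, path) {
  e <- network$edges
  directed <- any(e$direction %in% c("from->to", "to->from"))
  ed <- e
  swap <- ed$direction == "to->from"
  tmp <- ed$from[swap]; ed$from[swap] <- ed$to[swap]; ed$to[swap] <- tmp
  g <- igraph::graph_from_data_frame(
    ed[, c("from", "to", "net_fc", "direction")],
    directed = directed,
    vertices = data.frame(name = rownames(network$net)))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
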