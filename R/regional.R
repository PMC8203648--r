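# Atlas labeling, region time courses, activation-probability region
# selection, event-related averaging with repeated-measures group
# comparison, and maximum-amplitude maps.

#' Region time courses container
#'
#' @param mat region x time numeric matrix with region names as rownames.
#' @param counts per-region active-voxel counts (named; defaults to 1).
#' @param subject subject identifier.
#' @param tr repetition time of the time courses in seconds.
#' @param omitted names of regions without any active voxel.
#' @return Object of class `region_timecourses`.
#' @export
region_timecourses_obj <- function(mat, counts = NULL, subject = NA_character_,
                                   tr = NA_real_, omitted = character()) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  if (is.null(counts)) counts <- stats::setNames(rep(1L, nrow(mat)), rownames(mat))
  structure(list(mat = mat, counts = counts, subject = subject, tr = tr,
                 omitted = omitted),
            class = "region_timecourses")
}

#' @export
print.region_timecourses <- function(x, ...) {
  cat(sprintf("<region_timecourses> %s: %d regions x %d timepoints (%d omitted)\n",
              x$subject, nrow(x$mat), ncol(x$mat), length(x$omitted)))
  invisible(x)
}

#' Region-averaged time courses of significantly activated voxels
#'
#' For each atlas region, averages (unweighted) the time courses of its
#' voxels inside the activation mask. Regions without any active voxel are
#' omitted from the matrix and listed in `omitted`.
#'
#' @param series a [volume_series()].
#' @param mask 3D logical array of significant voxels (e.g. an
#'   [activation_mask()], or a union of per-predictor masks).
#' @param atlas an [atlas_labels()] matching the series geometry.
#' @param subject subject identifier carried through to the result.
#' @return A [region_timecourses_obj()].
#' @export
region_timecourses <- function(series, mask, atlas, subject = NA_character_) {
  stopifnot(inherits(series, "volume_series"), inherits(atlas, "atlas_labels"))
  d <- dim(series$data)
  if (!identical(as.integer(d[1:3]), as.integer(dim(atlas$labels))))
    stop("atlas geometry ", paste(dim(atlas$labels), collapse = "x"),
         " does not match series geometry ", paste(d[1:3], collapse = "x"))
  if (!identical(as.integer(dim(mask)), as.integer(d[1:3])))
    stop("mask geometry does not match series geometry")
  lab <- as.integer(atlas$labels)
  act <- as.logical(mask)
  flat <- matrix(series$data, ncol = d[4])
  ids <- atlas$regions$id
  rows <- list(); counts <- integer(0); kept <- character(0)
  omitted <- character(0)
  for (i in seq_along(ids)) {
    v <- which(lab == ids[i] & act)
    if (length(v)) {
      rows[[length(rows) + 1L]] <-
        if (length(v) == 1L) flat[v, ] else colMeans(flat[v, , drop = FALSE])
      counts <- c(counts, length(v))
      kept <- c(kept, atlas$regions$name[i])
    } else {
      omitted <- c(omitted, atlas$regions$name[i])
    }
  }
  mat <- if (length(rows)) do.call(rbind, rows) else
    matrix(numeric(0), 0, d[4])
  rownames(mat) <- kept
  region_timecourses_obj(mat, stats::setNames(counts, kept), subject = subject,
                         tr = series$tr, omitted = omitted)
}

#' Activation-probability region selection
#'
#' A region counts as active in one subject x condition entry when it has
#' at least one significantly activated voxel. Its activation probability
#' is the fraction of entries in which it is active; regions at or above
#' `threshold` are selected, in fixed atlas order.
#'
#' @param flags region x entry logical matrix (rows named by region;
#'   columns are subject x condition entries). Build it from per-subject
#'   [region_timecourses()] results, e.g. via [activation_flags()].
#' @param threshold selection threshold on the probability (default 0.5).
#' @return Character vector of selected region names, with the per-region
#'   probabilities as attribute `probability`.
#' @export
activation_probability <- function(flags, threshold = 0.5) {
  stopifnot(is.matrix(flags), is.logical(flags), ncol(flags) >= 1)
  prob <- rowMeans(flags)
  sel <- rownames(flags)[prob >= threshold]
  structure(sel, probability = prob)
}

#' Region activity flags from per-subject time courses
#'
#' @param tc_list list of [region_timecourses_obj()] (one per subject x
#'   condition entry).
#' @param region_names full region name vector (rows of the output).
#' @return region x entry logical matrix for [activation_probability()].
#' @export
activation_flags <- function(tc_list, region_names) {
  flags <- vapply(tc_list, function(tc) region_names %in% rownames(tc$mat),
                  logical(length(region_names)))
  flags <- matrix(flags, nrow = length(region_names),
                  dimnames = list(region_names, NULL))
  flags
}

#' Event-related average profiles
#'
#' Aligns windows of `pre` timepoints before each event onset, the
#' stimulation period itself, and `post` timepoints after it, for all
#' events of one condition, and averages them. Each window is expressed as
#' percent signal change from the mean of its own pre period. Events whose
#' window would be truncated by the record boundaries are excluded with a
#' warning.
#'
#' @param tc a [region_timecourses_obj()].
#' @param paradigm the [paradigm()] the series was acquired under (same
#'   effective TR as `tc`).
#' @param condition event kind to average (`"heat"`, `"laser"`, `"costim"`).
#' @param pre,post number of timepoints before onset / after the
#'   stimulation period (defaults 10 and 15).
#' @return Object of class `era_profile`: list with `profile` (region x
#'   window matrix, % signal change), `window` (`pre`, `stim`, `post`
#'   lengths), `n_events`, `tr`.
#' @export
event_related_average <- function(tc, paradigm, condition = "costim",
                                  pre = 10, post = 15) {
  stopifnot(inherits(tc, "region_timecourses"), inherits(paradigm, "paradigm"))
  tr <- paradigm$tr
  nt <- ncol(tc$mat)
  ev <- paradigm$events[paradigm$events$kind == condition, , drop = FALSE]
  if (!nrow(ev)) stop("paradigm has no ", condition, " events")
  stim_len <- ceiling((ev$ramp[1] + ev$plateau[1]) / tr)
  wlen <- pre + stim_len + post
  onset_vol <- round(ev$onset / tr) + 1L
  starts <- onset_vol - pre
  ends <- starts + wlen - 1L
  ok <- starts >= 1L & ends <= nt
  if (any(!ok))
    warning(sum(!ok), " event(s) excluded: window truncated by record boundary")
  if (!any(ok)) stop("no complete event window inside the time course")
  acc <- matrix(0, nrow(tc$mat), wlen)
  for (i in which(ok)) {
    win <- tc$mat[, starts[i]:ends[i], drop = FALSE]
    base <- rowMeans(win[, seq_len(pre), drop = FALSE])
    acc <- acc + 100 * (win - base) / base
  }
  profile <- acc / sum(ok)
  rownames(profile) <- rownames(tc$mat)
  structure(list(profile = profile,
                 window = c(pre = pre, stim = stim_len, post = post),
                 n_events = sum(ok), tr = tr),
            class = "era_profile")
}

#' Group comparison of event-related averages
#'
#' Per region, a repeated-measures ANOVA over the event-related window
#' (within factor: timepoint; between factor: group; subjects as repeated
#' units), followed by Tukey HSD on the group factor and Bonferroni
#' correction across regions. Reports the difference of subject-mean
#' window responses (treated minus control) with its SEM and a direction
#' label (`reduced` / `enhanced`).
#'
#' @param profiles_control,profiles_treated lists of [event_related_average()]
#'   results, one per subject (at least 2 per group). Regions absent from a
#'   subject's profile are excluded pairwise.
#' @param alpha significance level after Bonferroni correction.
#' @return Data frame: region, n_control, n_treated, diff (treated -
#'   control mean % signal change), sem, p (RM-ANOVA group effect),
#'   p_tukey, p_bonferroni, direction, significant.
#' @export
compare_era_groups <- function(profiles_control, profiles_treated,
                               alpha = 0.05) {
  if (length(profiles_control) < 2 || length(profiles_treated) < 2)
    stop("each group needs at least 2 subjects")
  all_prof <- c(profiles_control, profiles_treated)
  grp <- rep(c("control", "treated"),
             c(length(profiles_control), length(profiles_treated)))
  regions <- sort(unique(unlist(lapply(all_prof, function(p) rownames(p$profile)))))
  res <- lapply(regions, function(rg) {
    have <- vapply(all_prof, function(p) rg %in% rownames(p$profile), logical(1))
    g <- grp[have]
    if (sum(g == "control") < 2 || sum(g == "treated") < 2) return(NULL)
    mats <- lapply(all_prof[have], function(p) p$profile[rg, ])
    wlen <- length(mats[[1]])
    long <- data.frame(
      value = unlist(mats),
      time = factor(rep(seq_len(wlen), times = length(mats))),
      subject = factor(rep(seq_along(mats), each = wlen)),
      group = factor(rep(g, each = wlen), levels = c("control", "treated")))
    sub_means <- tapply(long$value, long$subject, mean)
    sub_group <- factor(tapply(as.character(long$group), long$subject, `[`, 1),
                        levels = c("control", "treated"))
    mc <- mean(sub_means[sub_group == "control"])
    mt <- mean(sub_means[sub_group == "treated"])
    sem <- sqrt(stats::var(sub_means[sub_group == "control"]) / sum(sub_group == "control") +
                  stats::var(sub_means[sub_group == "treated"]) / sum(sub_group == "treated"))
    # RM-ANOVA: group tested in the between-subject stratum
    a <- stats::aov(value ~ group * time + Error(subject), data = long)
    s <- summary(a)
    btw <- s[["Error: subject"]][[1]]
    p_grp <- btw["group", "Pr(>F)"]
    if (is.null(p_grp) || !length(p_grp)) p_grp <- NA_real_
    # Tukey HSD on the group factor (subject-mean responses)
    p_tukey <- tryCatch({
      th <- stats::TukeyHSD(stats::aov(sub_means ~ sub_group))
      unname(th$sub_group[1, "p adj"])
    }, error = function(e) NA_real_)
    data.frame(region = rg,
               n_control = sum(sub_group == "control"),
               n_treated = sum(sub_group == "treated"),
               diff = mt - mc, sem = sem, p = p_grp, p_tukey = p_tukey,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) stop("no region present in at least 2 subjects per group")
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out$direction <- ifelse(out$diff < 0, "reduced", "enhanced")
  out$direction[out$diff == 0] <- "none"
  out$significant <- !is.na(out$p_bonferroni) & out$p_bonferroni <= alpha &
    !is.na(out$p_tukey) & out$p_tukey <= alpha
  rownames(out) <- NULL
  out
}

#' Maximum BOLD amplitude map
#'
#' Per voxel (or per region when given region time courses), the maximum
#' percent-signal-change deviation from baseline inside the given
#' condition's event windows. Baseline is the mean signal before the first
#' event onset of any kind; the window of an event extends from its onset
#' to `settle_s` seconds past stimulus offset so the haemodynamic peak is
#' captured, and never into the next event of another kind beyond that.
#'
#' @param x a [volume_series()] or a [region_timecourses_obj()].
#' @param paradigm the [paradigm()].
#' @param condition event kind.
#' @param settle_s seconds past stimulus offset included in each window.
#' @return For a series: 3D array of amplitudes (% signal change, max
#'   deviation magnitude). For region time courses: named numeric vector.
#' @export
amplitude_map <- function(x, paradigm, condition = "costim", settle_s = 12) {
  stopifnot(inherits(paradigm, "paradigm"))
  ev <- paradigm$events[paradigm$events$kind == condition, , drop = FALSE]
  if (!nrow(ev)) stop("paradigm has no ", condition, " events")
  tr <- paradigm$tr
  if (inherits(x, "volume_series")) {
    d <- dim(x$data)
    flat <- matrix(x$data, ncol = d[4])
  } else if (inherits(x, "region_timecourses")) {
    flat <- x$mat
    d <- NULL
  } else stop("x must be a volume_series or region_timecourses")
  nt <- ncol(flat)
  first_onset <- min(paradigm$events$onset)
  n_base <- max(1L, floor(first_onset / tr))
  base <- rowMeans(flat[, seq_len(min(n_base, nt)), drop = FALSE])
  in_win <- rep(FALSE, nt)
  for (i in seq_len(nrow(ev))) {
    a <- round(ev$onset[i] / tr) + 1L
    b <- min(nt, round((ev$onset[i] + ev$ramp[i] + ev$plateau[i] + settle_s) / tr) + 1L)
    if (a <= nt) in_win[a:b] <- TRUE
  }
  dev <- abs(100 * (flat[, in_win, drop = FALSE] - base) / base)
  amp <- apply(dev, 1, max)
  if (!is.null(d)) array(amp, d[1:3]) else stats::setNames(amp, rownames(flat))
}

#' Write ERA group statistics or profiles as tidy TSV
#'
#' @param x a data frame (e.g. from [compare_era_groups()]).
#' @param path output TSV path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
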