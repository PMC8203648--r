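# Run configuration, end-to-end pipeline and reporting. Every analysis
# parameter defaults to the protocol value (100 s stimulus interval, 20 s
# stimuli with 5 s ramp, TR 2000 ms resampled to TR_eff 4000 ms, FDR
# q = 0.05, activation-probability threshold 0.5, 500 edges per channel,
# alpha 0.05); the simulated geometry defaults to desk scale.

#' Default run configuration
#'
#' Nested list of all pipeline parameters. Analysis parameters default to
#' the reference protocol values; the simulation geometry defaults to desk
#' scale (16 x 16 x 8 grid, 20 regions, 975 effective volumes at TR 4 s).
#' Set `acquisition$raw_timing = TRUE` to simulate at acquisition timing
#' (TR 2 s, 1950 volumes) and let the pipeline discard the first two
#' volumes and pairwise-average to TR_eff 4 s.
#'
#' @param seed master seed; all randomness in a run flows from it.
#' @return A `run_config` list.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = seed,
    paradigm = list(type = "costim", n_heat = 16, interval = 100,
                    stim_duration = 20, ramp = 5, heat_magnitude = 50),
    acquisition = list(tr = 4, n_volumes = 975, raw_timing = FALSE,
                       raw_tr = 2, raw_n_volumes = 1950,
                       grid = c(16, 16, 8)),
    simulate = list(n_regions = 20, baseline = 100, noise_sd = 0.2,
                    amplitudes = list(heat = 1.2, laser = 0.4, costim = 1.5),
                    act_prob = 1,
                    group_multipliers = list(control = 1, activated = 1),
                    coupling = NULL,
                    group_sizes = list(control = 5, activated = 9)),
    preprocess = list(discard = 2, pairwise = TRUE, fwhm_vox = 2,
                      n_cycles = 9, smooth_fwhm_s = 12),
    glm = list(q = 0.05),
    regional = list(act_threshold = 0.5, era_pre = 10, era_post = 15,
                    era_condition = "costim", alpha = 0.05),
    connectivity = list(n_pos = 500, n_neg = 500, test = "homoscedastic",
                        alpha = 0.05, display_threshold = 6,
                        n_composites = 5, membership = NULL),
    hrf = list(time_to_peak = 5, undershoot_peak = 15,
               response_undershoot_ratio = 6, dispersion = 1,
               u_dispersion = 1)),
    class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param config a `run_config` list.
#' @param path YAML file path.
#' @rdname config_yaml
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname config_yaml
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$acquisition$grid <- as.numeric(unlist(cfg$acquisition$grid))
  structure(cfg, class = "run_config")
}

# Composite abbreviations used in the reference summary networks.
.composite_abbrevs <- c("Am", "BFB", "BNST", "Bs", "CE", "Cer", "CPu",
                        "cxAss", "cxCg", "cxIns", "cxM", "cxS1", "cxS2",
                        "Hc", "Hy", "lTh", "mTh", "PAG")

#' Default composite-node membership
#'
#' Assigns atlas regions to `n_composites` named composite nodes in
#' contiguous blocks, using the standard summary-network abbreviations
#' (Am, BFB, BNST, ...; see `inst/extdata/composite_nodes.tsv` for the
#' full names) as node labels. Purely positional: the synthetic atlas has
#' no anatomy, so the map only fixes a non-overlapping covering grouping.
#'
#' @param region_names atlas region names.
#' @param n_composites number of composite nodes (at most 18).
#' @return Named character vector region -> composite.
#' @export
default_membership <- function(region_names, n_composites = 5) {
  stopifnot(n_composites >= 1, n_composites <= length(.composite_abbrevs),
            n_composites <= length(region_names))
  comp <- .composite_abbrevs[((seq_along(region_names) - 1) %% n_composites) + 1]
  stats::setNames(comp, region_names)
}

# Build the effect_spec described by a run_config.
.config_effect_spec <- function(cfg) {
  n <- cfg$simulate$n_regions
  amp <- do.call(cbind, lapply(cfg$simulate$amplitudes, rep_len, n))
  coupling <- cfg$simulate$coupling
  if (!is.null(coupling)) coupling <- as.data.frame(coupling)
  effect_spec(n_regions = n, amplitudes = amp,
              group_multipliers = unlist(cfg$simulate$group_multipliers),
              coupling = coupling,
              noise_sd = cfg$simulate$noise_sd,
              act_prob = cfg$simulate$act_prob,
              baseline = cfg$simulate$baseline)
}

# Paradigm at the timing the data are simulated at.
.config_paradigm <- function(cfg) {
  acq <- cfg$acquisition
  tr <- if (isTRUE(acq$raw_timing)) acq$raw_tr else acq$tr
  nv <- if (isTRUE(acq$raw_timing)) acq$raw_n_volumes else acq$n_volumes
  p <- cfg$paradigm
  if (identical(p$type, "costim")) {
    build_costim_paradigm(n_heat = p$n_heat, interval = p$interval,
                          stim_duration = p$stim_duration, ramp = p$ramp,
                          tr = tr, n_volumes = nv,
                          heat_magnitude = p$heat_magnitude)
  } else if (identical(p$type, "wt_heat")) {
    build_wt_heat_paradigm(temperatures = unlist(p$temperatures),
                           n_sets = p$n_sets, initial_rest = p$initial_rest,
                           stim_duration = p$stim_duration,
                           interval = p$interval, ramp = p$ramp,
                           tr = tr, n_volumes = nv)
  } else stop("unknown paradigm type: ", p$type)
}

#' Run the full pipeline on a simulated cohort
#'
#' Executes simulate -> preprocess -> GLM -> regionalize -> event-related
#' averaging and group comparison -> differential FC network, entirely
#' driven by the configuration; deterministic given `config$seed`. Stage
#' failures halt with the stage name and offending subject.
#'
#' @param config a [default_config()]-style `run_config`.
#' @param verbose print stage progress.
#' @return A result bundle (class `pipeline_result`): list with `config`,
#'   `paradigm`, `atlas`, `cohort_manifest`, `region_tc` (per subject),
#'   `activation` (flags, probabilities, selected regions), `era`
#'   (profiles and group table), `fc` (subject matrices, group means,
#'   thresholded sets, differential matrix), `network` (composite
#'   network), `amplitude` (per-subject region amplitude vectors).
#' @export
run_pipeline <- function(config = default_config(), verbose = FALSE) {
  cfg <- config
  say <- function(...) if (verbose) message(...)
  stage <- function(name, subject, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed",
           if (!is.na(subject)) paste0(" for subject ", subject) else "",
           ": ", conditionMessage(e), call. = FALSE))
  }
  hrf <- do.call(hrf_params, cfg$hrf)
  par_sim <- stage("paradigm", NA, .config_paradigm(cfg))
  spec <- stage("effect_spec", NA, .config_effect_spec(cfg))
  say("simulating cohort")
  atlas <- stage("atlas", NA,
                 make_atlas(cfg$acquisition$grid, cfg$simulate$n_regions,
                            seed = cfg$seed))
  cohort <- stage("simulate", NA,
                  simulate_cohort(par_sim, atlas, spec,
                                  group_sizes = unlist(cfg$simulate$group_sizes),
                                  seed = cfg$seed, hrf = hrf))
  groups <- cohort$manifest$group
  ids <- cohort$manifest$subject
  ctrl_name <- names(cfg$simulate$group_sizes)[1]

  # preprocessing + GLM + regionalization, per subject
  say("preprocessing and GLM")
  pp <- cfg$preprocess
  par_eff <- par_sim
  design <- NULL
  region_tc <- list(); masks <- list(); amp_maps <- list()
  flags_entries <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]
    s <- cohort$subjects[[id]]$series
    stage("preprocess", id, {
      if (isTRUE(cfg$acquisition$raw_timing)) {
        s <- discard_initial(s, pp$discard)
        par_eff <- shift_paradigm(par_sim, pp$discard)
        if (isTRUE(pp$pairwise)) {
          s <- pairwise_average(s)
          par_eff <- paradigm(par_eff$events, tr = 2 * par_eff$tr,
                              n_volumes = dim(s$data)[4])
        }
      }
      s <- register_identity(s)
      if (pp$fwhm_vox > 0) s <- spatial_smooth(s, pp$fwhm_vox)
      vox_mean <- rowMeans(matrix(s$data, ncol = dim(s$data)[4]))
      s <- temporal_filter(s, pp$n_cycles, pp$smooth_fwhm_s)
      # restore baseline level so percent-signal-change baselines are defined
      s$data <- s$data + array(vox_mean, dim(s$data))
    })
    if (is.null(design)) design <- design_matrix(par_eff, params = hrf)
    g <- stage("glm", id, fit_glm(s, design))
    brain <- atlas$labels > 0
    pred_masks <- lapply(g$stimulus_columns, function(k)
      activation_mask(g, k, q = cfg$glm$q, brain_mask = brain))
    names(pred_masks) <- g$stimulus_columns
    union_mask <- Reduce(`|`, lapply(pred_masks, function(m) unclass(m) > 0))
    tc <- stage("regionalize", id,
                region_timecourses(s, union_mask, atlas, subject = id))
    region_tc[[id]] <- tc
    masks[[id]] <- pred_masks
    # region activity flags per predictor (subject x condition entries)
    lab <- as.integer(atlas$labels)
    for (k in names(pred_masks)) {
      act <- as.logical(pred_masks[[k]])
      fl <- vapply(atlas$regions$id, function(rid)
        any(act[lab == rid]), logical(1))
      flags_entries[[paste(id, k, sep = ".")]] <-
        stats::setNames(fl, atlas$regions$name)
    }
    amp_maps[[id]] <- stage("amplitude", id,
                            amplitude_map(tc, par_eff,
                                          cfg$regional$era_condition))
  }

  say("region selection and event-related averaging")
  flags <- do.call(cbind, flags_entries)
  selected <- activation_probability(flags, cfg$regional$act_threshold)
  era <- lapply(region_tc, function(tc)
    event_related_average(tc, par_eff, cfg$regional$era_condition,
                          pre = cfg$regional$era_pre,
                          post = cfg$regional$era_post))
  era_table <- compare_era_groups(era[groups == ctrl_name],
                                  era[groups != ctrl_name],
                                  alpha = cfg$regional$alpha)

  say("functional connectivity")
  sel_tc <- lapply(region_tc, function(tc) {
    keep <- intersect(rownames(tc$mat), selected)
    region_timecourses_obj(tc$mat[keep, , drop = FALSE],
                           tc$counts[keep], tc$subject, tc$tr)
  })
  fc_sub <- lapply(sel_tc, function(tc)
    .pad_fc(fc_matrix(remove_global_mean(tc)), selected))
  fc_control <- fc_sub[groups == ctrl_name]
  fc_treated <- fc_sub[groups != ctrl_name]
  mean_control <- group_mean_fc(fc_control)
  mean_treated <- group_mean_fc(fc_treated)
  thr_control <- suppressWarnings(
    threshold_fc(mean_control, selected, cfg$connectivity$n_pos,
                 cfg$connectivity$n_neg))
  thr_treated <- suppressWarnings(
    threshold_fc(mean_treated, selected, cfg$connectivity$n_pos,
                 cfg$connectivity$n_neg))
  dfc <- diff_fc(fc_control, fc_treated, list(thr_control, thr_treated),
                 test = cfg$connectivity$test, alpha = cfg$connectivity$alpha)
  membership <- cfg$connectivity$membership
  if (is.null(membership))
    membership <- default_membership(atlas$regions$name,
                                     cfg$connectivity$n_composites)
  membership_used <- membership[dfc$regions]
  network <- aggregate_composite(dfc, membership_used,
                                 cfg$connectivity$display_threshold)
  structure(list(config = cfg, paradigm = par_eff, atlas = atlas,
                 cohort_manifest = cohort$manifest,
                 region_tc = region_tc, masks = masks,
                 activation = list(flags = flags,
                                   probability = attr(selected, "probability"),
                                   selected = as.character(selected)),
                 era = list(profiles = era, table = era_table),
                 fc = list(subject = fc_sub, mean_control = mean_control,
                           mean_treated = mean_treated,
                           thresholded = list(control = thr_control,
                                              treated = thr_treated),
                           diff = dfc),
                 network = network,
                 amplitude = amp_maps),
            class = "pipeline_result")
}

# Pad a subject FC matrix to a fixed region set (NA where undefined).
.pad_fc <- function(fc, regions) {
  out <- matrix(NA_real_, length(regions), length(regions),
                dimnames = list(regions, regions))
  have <- intersect(rownames(fc), regions)
  out[have, have] <- fc[have, have]
  out
}

#' Summary tables for a pipeline result
#'
#' @param bundle a [run_pipeline()] result.
#' @return List with `era` (group-difference table), `net_fc` (composite
#'   net-FC matrix), `edges` (displayed composite edges), `selected`
#'   (region selection with activation probabilities) and `summary`
#'   (character lines).
#' @export
report <- function(bundle) {
  stopifnot(inherits(bundle, "pipeline_result"))
  e <- bundle$network$edges
  lines <- c(
    sprintf("subjects: %d (%s)", nrow(bundle$cohort_manifest),
            paste(sprintf("%s: %d",
                          names(table(bundle$cohort_manifest$group)),
                          table(bundle$cohort_manifest$group)),
                  collapse = ", ")),
    sprintf("regions selected (activation probability >= %g): %d of %d",
            bundle$config$regional$act_threshold,
            length(bundle$activation$selected),
            nrow(bundle$atlas$regions)),
    sprintf("significant ERA group differences: %d region(s)",
            sum(bundle$era$table$significant)),
    if (nrow(e) == 0)
      sprintf("differential network: zero significant edges above |net| > %g",
              bundle$network$display_threshold)
    else
      sprintf("differential network: %d composite edge(s) above |net| > %g",
              nrow(e), bundle$network$display_threshold))
  list(era = bundle$era$table,
       net_fc = bundle$network$net,
       edges = e,
       selected = data.frame(region = names(bundle$activation$probability),
                             probability = unname(bundle$activation$probability),
                             selected = names(bundle$activation$probability) %in%
                               bundle$activation$selected),
       summary = lines)
}

#' Write a pipeline report to disk
#'
#' Writes the ERA table, net-FC matrix, displayed edges and region
#' selection as TSV, the composite network as GraphML, and a plain-text
#' summary, plus a JSON provenance sidecar echoing every parameter.
#'
#' @param bundle a [run_pipeline()] result.
#' @param dir output directory.
#' @export
write_report <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rep <- report(bundle)
  write_tsv(rep$era, file.path(dir, "era_group_differences.tsv"))
  write_fc_tsv(rep$net_fc, file.path(dir, "net_fc_matrix.tsv"))
  write_tsv(rep$edges, file.path(dir, "network_edges.tsv"))
  write_tsv(rep$selected, file.path(dir, "region_selection.tsv"))
  if (nrow(rep$edges))
    write_network_graphml(bundle$network, file.path(dir, "network.graphml"))
  writeLines(rep$summary, file.path(dir, "summary.txt"))
  jsonlite::write_json(unclass(bundle$config),
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
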