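test_that("synthetic atlas partitions the brain mask into contiguous parcels", {
  atlas <- make_atlas(c(12, 12, 6), n_regions = 10, seed = 4)
  lab <- atlas$labels
  counts <- table(lab[lab > 0])
  expect_length(counts, 10)
  expect_true(all(counts >= 1))
  # partition: every brain voxel carries exactly one label by construction;
  # contiguity: each parcel is one 6-connected component
  for (r in 1:10) {
    vox <- which(lab == r, arr.ind = TRUE)
    seen <- rep(FALSE, nrow(vox))
    seen[1] <- TRUE
    frontier <- 1L
    while (length(frontier)) {
      nxt <- integer(0)
      for (f in frontier) {
        adj <- which(!seen &
                       rowSums(abs(sweep(vox, 2, vox[f, ]))) == 1)
        seen[adj] <- TRUE
        nxt <- c(nxt, adj)
      }
      frontier <- nxt
    }
    expect_true(all(seen), label = sprintf("parcel %d contiguous", r))
  }
  expect_identical(make_atlas(c(12, 12, 6), 10, seed = 4)$labels, lab)
  expect_false(identical(make_atlas(c(12, 12, 6), 10, seed = 5)$labels, lab))
  expect_error(make_atlas(c(4, 4, 2), n_regions = 500), "cannot place")
})

test_that("atlas supports the reference granularity of 196 regions", {
  atlas <- make_atlas(c(32, 32, 12), n_regions = 196, seed = 1)
  expect_equal(nrow(atlas$regions), 196)
  expect_length(table(atlas$labels[atlas$labels > 0]), 196)
})

test_that("noise-free, effect-free subjects are constant at baseline", {
  atlas <- tiny_atlas()
  p <- build_costim_paradigm(n_heat = 2, interval = 50, tr = 4,
                             n_volumes = 100, initial_rest = 50)
  spec <- effect_spec(6, amplitudes = 0, noise_sd = 0)
  sub <- simulate_subject(p, atlas, spec, "control", seed = 1)
  expect_true(all(sub$series$data == 100))
  expect_true(all(sub$truth$region_signals == 100))
})

test_that("planted response amplitude appears as the event-locked peak", {
  atlas <- tiny_atlas()
  p <- build_costim_paradigm()
  a <- 2.5
  spec <- effect_spec(6, amplitudes = matrix(a, 6, 1,
                                             dimnames = list(NULL, "costim")),
                      noise_sd = 0)
  sub <- simulate_subject(p, atlas, spec, "control", seed = 1)
  x <- design_matrix(p, drift = FALSE)[, "costim"]
  expected_peak <- a * max(x)   # % change over the flat baseline of 100
  tc <- sub$truth$region_signals[1, ]
  era <- event_related_average(
    region_timecourses_obj(sub$truth$region_signals, tr = 4),
    p, "costim", pre = 10, post = 15)
  expect_equal(max(era$profile[1, ]), expected_peak, tolerance = 1e-8)
})

test_that("planted couplings produce the planted correlations", {
  atlas <- tiny_atlas()
  p <- build_costim_paradigm()
  spec <- effect_spec(6, amplitudes = 0, noise_sd = 0.1,
                      coupling = data.frame(region_a = 1, region_b = 2,
                                            channel = "positive",
                                            group = "control", strength = 0.9))
  rs <- sapply(1:20, function(s) {
    sub <- simulate_subject(p, atlas, spec, "control", seed = s,
                            voxel_level = FALSE)
    cor(sub$truth$region_signals[1, ], sub$truth$region_signals[2, ])
  })
  expect_true(all(rs > 0.5))
  # negative channel flips the sign
  spec_n <- effect_spec(6, amplitudes = 0, noise_sd = 0.1,
                        coupling = data.frame(region_a = 1, region_b = 2,
                                              channel = "negative",
                                              group = "control", strength = 0.9))
  sub <- simulate_subject(p, atlas, spec_n, "control", seed = 1,
                          voxel_level = FALSE)
  expect_lt(cor(sub$truth$region_signals[1, ], sub$truth$region_signals[2, ]),
            -0.5)
})

test_that("cohorts are deterministic and use the stated group sizes", {
  atlas <- tiny_atlas()
  p <- build_costim_paradigm(n_heat = 2, interval = 50, tr = 4,
                             n_volumes = 100, initial_rest = 50)
  spec <- effect_spec(6, amplitudes = 1, noise_sd = 0.2)
  co <- simulate_cohort(p, atlas, spec, group_sizes = c(control = 5, activated = 9),
                        seed = 7, voxel_level = FALSE)
  expect_equal(table(co$manifest$group),
               table(factor(rep(c("activated", "control"), c(9, 5)))))
  co2 <- simulate_cohort(p, atlas, spec, group_sizes = c(control = 5, activated = 9),
                         seed = 7, voxel_level = FALSE)
  expect_identical(
    lapply(co$subjects, function(s) s$truth$region_signals),
    lapply(co2$subjects, function(s) s$truth$region_signals))
  co3 <- simulate_cohort(p, atlas, spec, group_sizes = c(control = 5, activated = 9),
                         seed = 8, voxel_level = FALSE)
  expect_false(identical(co$subjects[[1]]$truth$region_signals,
                         co3$subjects[[1]]$truth$region_signals))
})

test_that("activation probability gates region responses per subject", {
  atlas <- tiny_atlas()
  p <- build_costim_paradigm(n_heat = 2, interval = 50, tr = 4,
                             n_volumes = 100, initial_rest = 50)
  spec <- effect_spec(6, amplitudes = 2, noise_sd = 0, act_prob = 0.5)
  gates <- sapply(1:40, function(s)
    simulate_subject(p, atlas, spec, "control", seed = s,
                     voxel_level = FALSE)$truth$gates)
  expect_equal(mean(gates), 0.5, tolerance = 0.12)
  # gated-off regions stay at baseline
  sub <- simulate_subject(p, atlas, spec, "control", seed = 2,
                          voxel_level = FALSE)
  off <- which(sub$truth$gates == 0)
  if (length(off))
    expect_true(all(sub$truth$region_signals[off, ] == 100))
})

test_that("cohort export writes NIfTI series, truth sidecars and a manifest", {
  atlas <- make_atlas(c(6, 6, 2), 3, seed = 1)
  p <- build_costim_paradigm(n_heat = 2, interval = 50, tr = 4,
                             n_volumes = 60, initial_rest = 50)
  spec <- effect_spec(3, amplitudes = 1, noise_sd = 0.2)
  co <- simulate_cohort(p, atlas, spec, group_sizes = c(control = 2, activated = 2),
                        seed = 1)
  dir <- tempfile()
  man <- write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  expect_true(file.exists(file.path(dir, "atlas.nii.gz")))
  expect_true(all(file.exists(man$series_path)))
  expect_true(all(file.exists(man$truth_path)))
  s <- read_series_nifti(man$series_path[1])
  expect_equal(s$data, co$subjects[[man$subject[1]]]$series$data,
               tolerance = 1e-6)
  truth <- jsonlite::fromJSON(man$truth_path[1])
  expect_equal(truth$group, man$group[1])
})
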