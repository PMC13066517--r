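small_config <- function(...) {
  simulation_config(n_ancestors = 20L, seq_length = 36L, n_participants = 4L,
                    depth_mean = 5000, abundance_sigma = 1, mutation_rate = 0,
                    seed = 42L, ...)
}

test_that("library generation: distinct sequences, normalized proportions, determinism", {
  cfg <- simulation_config(n_ancestors = 3L, seq_length = 36L, seed = 1L)
  lib <- generate_library(cfg)
  expect_length(lib$ancestors, 3)
  expect_false(anyDuplicated(lib$ancestors) > 0)
  expect_true(all(nchar(lib$ancestors) == 36))
  expect_true(all(strsplit(paste(lib$ancestors, collapse = ""), "")[[1]] %in%
                    c("A", "C", "G", "U")))
  expect_equal(sum(lib$baseline_proportions), 1)
  expect_identical(lib, generate_library(cfg))   # same seed, bit-identical

  flat <- generate_library(simulation_config(n_ancestors = 5L, abundance_sigma = 0, seed = 2L))
  expect_equal(flat$baseline_proportions, rep(0.2, 5))
})

test_that("well-separated libraries exceed the pairwise separation threshold", {
  cfg <- simulation_config(n_ancestors = 30L, seq_length = 36L,
                           well_separated = TRUE, seed = 3L)
  lib <- generate_library(cfg)
  d <- outer(seq_along(lib$ancestors), seq_along(lib$ancestors),
             function(i, j) dl_distance(lib$ancestors[i], lib$ancestors[j]))
  expect_true(all(d[upper.tri(d)] > 2 * cfg$max_edits_per_read))
  # infeasible separation request fails loudly
  tight <- simulation_config(n_ancestors = 50L, seq_length = 3L,
                             max_edits_per_read = 3L, well_separated = TRUE, seed = 4L)
  expect_error(generate_library(tight, max_attempts = 200L), "rejection sampling")
})

test_that("cohort generation: metadata design, determinism, proportions close", {
  cfg <- small_config()
  coh <- generate_cohort(cfg)
  expect_identical(nrow(coh$metadata), 4L * 4L)   # participants x timepoints
  expect_identical(sort(colnames(coh$counts)), sort(coh$metadata$sample_id))
  expect_true(all(table(coh$metadata$participant_id) == 4))
  expect_equal(unname(colSums(coh$truth$latent)), rep(1, 16), tolerance = 1e-12)
  expect_identical(coh, generate_cohort(cfg))     # fixed seed, bit-identical
})

test_that("without mutation the observed sequences are exactly the ancestors", {
  coh <- generate_cohort(small_config())
  expect_setequal(rownames(coh$counts), coh$truth$ancestors)
  expect_length(coh$truth$derived_map, 0)
})

test_that("planted fold change shifts latent proportions by the closed form", {
  # theta = 2 on ancestor 1 for elevated BMI, no noise: before renormalization
  # the elevated/normal latent ratio for that ancestor is exactly 2, and the
  # full latent vector matches direct computation baseline*fold/sum.
  cfg <- simulation_config(n_ancestors = 10L, n_participants = 40L,
                           p_elevated_bmi = 0.5, depth_mean = 1000,
                           abundance_sigma = 1, mutation_rate = 0, seed = 5L,
                           planted = list(planted_effect("bmi_group", "elevated", 1L,
                                                         fold_change = 2,
                                                         biological_sigma = 0)))
  lib <- generate_library(cfg)
  coh <- generate_cohort(cfg, lib)
  elevated <- coh$metadata$sample_id[coh$metadata$bmi_group == "elevated"]
  normal <- coh$metadata$sample_id[coh$metadata$bmi_group == "normal"]
  expect_gt(length(elevated), 0); expect_gt(length(normal), 0)
  w <- lib$baseline_proportions
  w_eff <- replace(w, 1, 2 * w[1])
  expected_elev <- w_eff / sum(w_eff)
  for (s in elevated)
    expect_equal(unname(coh$truth$latent[, s]), expected_elev, tolerance = 1e-12)
  for (s in normal)
    expect_equal(unname(coh$truth$latent[, s]), w, tolerance = 1e-12)
  # ratio of pre-normalization proportions is exactly the fold change
  ratio <- (coh$truth$latent[1, elevated[1]] / coh$truth$latent[2, elevated[1]]) /
    (coh$truth$latent[1, normal[1]] / coh$truth$latent[2, normal[1]])
  expect_equal(unname(ratio), 2, tolerance = 1e-12)
})

test_that("empirical proportions converge to latent proportions at high depth", {
  cfg <- simulation_config(n_ancestors = 50L, n_participants = 1L,
                           timepoints = "3d", depth_mean = 1e6,
                           abundance_sigma = 1, mutation_rate = 0, seed = 6L)
  coh <- generate_cohort(cfg)
  latent <- coh$truth$latent[, 1]
  names(latent) <- coh$truth$ancestors
  depth <- sum(coh$counts[, 1])
  emp <- coh$counts[, 1] / depth
  se <- sqrt(latent[rownames(coh$counts)] * (1 - latent[rownames(coh$counts)]) / depth)
  expect_true(all(abs(emp - latent[rownames(coh$counts)]) < 3 * se + 1e-12))
})

test_that("mutated reads stay within max_edits_per_read of their ancestor", {
  cfg <- simulation_config(n_ancestors = 15L, n_participants = 2L,
                           depth_mean = 3000, mutation_rate = 0.1,
                           max_edits_per_read = 3L, abundance_sigma = 0.5,
                           well_separated = TRUE, seed = 7L)
  coh <- generate_cohort(cfg)
  map <- coh$truth$derived_map
  expect_gt(length(map), 0)
  d <- dl_distance(names(map), unname(map))
  expect_true(all(d >= 1 & d <= 3))
  # read conservation: every read is either an ancestor read or a derived read
  expect_identical(sum(coh$counts), sum(coh$truth$pre_mutation_counts))
})

test_that("null simulation leaves group labels independent of counts by construction", {
  cfg <- small_config()
  expect_length(cfg$planted, 0)
  coh <- generate_cohort(cfg)
  expect_equal(max(apply(coh$truth$latent, 1, var)), 0, tolerance = 1e-30)
})

test_that("degenerate and invalid configurations are rejected", {
  expect_error(simulation_config(depth_mean = 0), "depth_mean")
  expect_error(simulation_config(mutation_rate = 1.5))
  expect_error(simulation_config(seq_length = 2L, max_edits_per_read = 3L))
  expect_error(simulation_config(planted = list(
    planted_effect("bmi_group", "elevated", 1:3),
    planted_effect("bmi_group", "normal", 3:4))), "overlap")
  expect_error(simulation_config(n_ancestors = 2L, planted = list(
    planted_effect("parity", "primiparous", 5L))), "beyond")
})
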