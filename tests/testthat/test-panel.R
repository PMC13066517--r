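toy_meta <- function(groups, timepoint = "3d") {
  data.frame(sample_id = names(groups), participant_id = names(groups),
             timepoint = timepoint, bmi_group = unname(groups),
             parity = "primiparous", cohort = "validation",
             stringsAsFactors = FALSE)
}

test_that("PCA scores match an independent eigendecomposition on a toy matrix", {
  set.seed(51)
  m <- matrix(rnorm(20, 1, 0.5), nrow = 5,
              dimnames = list(random_rna(5, 10), paste0("s", 1:4)))
  pca <- pca_panel(m, rownames(m))
  x <- scale(t(m), center = TRUE, scale = FALSE)
  eig <- eigen(crossprod(x) / (nrow(x) - 1), symmetric = TRUE)
  scores_oracle <- x %*% eig$vectors
  # with 4 samples the centered matrix has rank 3; compare the informative PCs
  for (k in 1:3) {
    a <- pca$scores[, k]; b <- scores_oracle[, k]
    expect_true(max(abs(a - b)) < 1e-8 || max(abs(a + b)) < 1e-8, info = paste("PC", k))
  }
  expect_equal(pca$explained_variance_ratio[1:3],
               (eig$values / sum(eig$values))[1:3], tolerance = 1e-8)
  expect_true(all(diff(pca$explained_variance_ratio) <= 1e-12))
  expect_lte(sum(pca$explained_variance_ratio), 1 + 1e-9)
})

test_that("two perfectly anti-correlated sequences give a rank-1 PCA", {
  base <- c(0.5, 1.5, 0.8, 1.2, 1.0)
  m <- rbind(A = base, B = 2 - base)
  rownames(m) <- c("ACGUACGUAC", "GGGGCCCCAA")
  colnames(m) <- paste0("s", 1:5)
  pca <- pca_panel(m, rownames(m))
  expect_equal(pca$explained_variance_ratio[1], 1, tolerance = 1e-12)
})

test_that("scores are sample-order invariant and the sign convention is deterministic", {
  set.seed(52)
  m <- matrix(rnorm(40, 1, 0.4), nrow = 5,
              dimnames = list(random_rna(5, 10), paste0("s", 1:8)))
  groups <- setNames(rep(c("normal", "elevated"), each = 4), colnames(m))
  meta <- toy_meta(groups)
  pca1 <- pca_panel(m, rownames(m), meta, "bmi_group", "normal", "elevated")
  perm <- sample(ncol(m))
  pca2 <- pca_panel(m[, perm], rownames(m), meta, "bmi_group", "normal", "elevated")
  expect_equal(pca1$scores[colnames(m), 1], pca2$scores[colnames(m), 1], tolerance = 1e-9)
  # orientation: study-group median >= reference median
  expect_gte(median(pca1$scores[5:8, 1]), median(pca1$scores[1:4, 1]))
  # repeated runs bit-identical
  expect_identical(pca1, pca_panel(m, rownames(m), meta, "bmi_group", "normal", "elevated"))
})

test_that("missing panel sequences reduce coverage with warning; all missing errors", {
  set.seed(53)
  m <- matrix(rnorm(30, 1, 0.2), nrow = 5,
              dimnames = list(random_rna(5, 10), paste0("s", 1:6)))
  panel <- c(rownames(m)[1:3], "AAAAAAAAAA")
  expect_warning(pca <- pca_panel(m, panel), "absent")
  expect_equal(pca$panel_coverage, 0.75)
  expect_setequal(pca$panel_used, rownames(m)[1:3])
  expect_error(suppressWarnings(pca_panel(m, c("AAAAAAAAAA", "CCCCCCCCCC"))), "no panel")
})

test_that("Wilcoxon rank-sum: exact small-sample case, identity, rank invariance", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)), 0.1)   # 2/C(6,3)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 9), c(1, 2, 9)), 1)
  set.seed(54)
  x <- rnorm(10); y <- rnorm(12, 0.5)
  p1 <- wilcoxon_rank_sum(x, y)
  p2 <- wilcoxon_rank_sum(exp(x), exp(y))    # strictly monotone transform
  expect_equal(p1, p2)
  expect_equal(p1, wilcox.test(x, y, exact = TRUE)$p.value)
  # large groups use the corrected normal approximation
  xl <- rnorm(40); yl <- rnorm(40)
  expect_equal(wilcoxon_rank_sum(xl, yl),
               wilcox.test(xl, yl, exact = FALSE, correct = TRUE)$p.value)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("validate_panel flags a planted BMI effect and stays null otherwise", {
  cfg <- simulation_config(
    n_ancestors = 150L, n_participants = 30L, timepoints = c("3d", "1m"),
    p_elevated_bmi = 0.5, depth_mean = 3e4, abundance_sigma = 1,
    mutation_rate = 0, seed = 55L,
    planted = list(planted_effect("bmi_group", "elevated", 1:8,
                                  fold_change = 1.8, biological_sigma = 0.2)))
  lib <- generate_library(cfg)
  coh <- generate_cohort(cfg, lib, "validation", seed = cfg$seed + 2L)
  norm <- normalize_counts(coh$counts)
  panel <- lib$ancestors[1:8]
  pv <- validate_panel(norm, coh$metadata, panel, grouping = "bmi_group")
  expect_s3_class(pv, "panel_validation")
  expect_equal(pv$panel_coverage, 1)
  expect_lt(pv$wilcoxon$p[1], 0.01)
  expect_gte(pv$group_medians[["elevated"]], pv$group_medians[["normal"]])
  expect_named(pv$group_variances)
  # group variances are the unbiased sample variances of the PC1 scores
  sc <- pv$scores
  expect_equal(pv$group_variances[["normal"]], var(sc$pc1[sc$group == "normal"]))
  # a grouping absent from metadata errors
  meta_bad <- coh$metadata
  meta_bad$bmi_group <- "normal"
  expect_error(validate_panel(norm, meta_bad, panel, grouping = "bmi_group"), "absent")
})

test_that("sampling-time validation tests each later timepoint vs reference plus 1m-vs-3m", {
  cfg <- simulation_config(
    n_ancestors = 100L, n_participants = 12L, depth_mean = 2e4,
    abundance_sigma = 1, mutation_rate = 0, seed = 56L,
    planted = list(planted_effect("sampling_time", "3m", 1:6,
                                  fold_change = 2.5, biological_sigma = 0.2)))
  lib <- generate_library(cfg)
  coh <- generate_cohort(cfg, lib)
  norm <- normalize_counts(coh$counts)
  pv <- validate_panel(norm, coh$metadata, lib$ancestors[1:6], grouping = "sampling_time")
  expect_identical(pv$wilcoxon$group1, c("3d", "3d", "3d", "1m"))
  expect_identical(pv$wilcoxon$group2, c("1m", "2m", "3m", "3m"))
  expect_lt(pv$wilcoxon$p[pv$wilcoxon$group2 == "3m"][1], 0.05)
})

test_that("panel aggregation beats the best single sequence for group separation", {
  # when only panel sequences carry the effect, PC1's point-biserial
  # correlation with the group label should usually exceed any single
  # sequence's
  wins <- 0L
  for (rep in 1:10) {
    cfg <- simulation_config(
      n_ancestors = 60L, n_participants = 24L, timepoints = "3d",
      p_elevated_bmi = 0.5, depth_mean = 2e4, abundance_sigma = 0.8,
      mutation_rate = 0, seed = 560L + rep,
      planted = list(planted_effect("bmi_group", "elevated", 1:10,
                                    fold_change = 1.4, biological_sigma = 0.25)))
    lib <- generate_library(cfg)
    coh <- generate_cohort(cfg, lib)
    norm <- normalize_counts(coh$counts)
    panel <- lib$ancestors[1:10]
    pca <- pca_panel(norm, panel, coh$metadata, "bmi_group", "normal", "elevated")
    lab <- as.integer(coh$metadata$bmi_group[match(rownames(pca$scores),
                                                   coh$metadata$sample_id)] == "elevated")
    r_pc1 <- abs(cor(pca$scores[, 1], lab))
    r_single <- max(abs(apply(norm$scaled[panel, rownames(pca$scores)], 1,
                              cor, y = lab)))
    if (r_pc1 > r_single) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})
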