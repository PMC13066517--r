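make_scaled <- function(values) {
  # values: list of per-sequence score vectors over samples s1..sn
  m <- do.call(rbind, values)
  rownames(m) <- random_rna(length(values), 12)
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  m
}

two_group_meta <- function(n1, n2) {
  data.frame(sample_id = paste0("s", seq_len(n1 + n2)),
             participant_id = paste0("p", seq_len(n1 + n2)),
             timepoint = "3d",
             bmi_group = rep(c("normal", "elevated"), c(n1, n2)),
             parity = "primiparous", cohort = "discovery")
}

test_that("binary-predictor OLS coefficient equals the group-mean difference", {
  set.seed(41)
  m <- make_scaled(list(c(0.99, 1.01, 1.29, 1.31), c(1, 1.2, 0.9, 1.1)))
  meta <- two_group_meta(2, 2)
  spec <- contrast_spec("bmi_group", "normal", "elevated")
  res <- ols_contrast(m, meta, spec)
  expect_equal(res$beta[1], 0.3)
  expect_true(abs(res$beta[1]) >= spec$coef_threshold)
  expect_identical(res$direction[1], "increased")
  # identical group distributions: beta 0, not descriptive
  m0 <- make_scaled(list(c(1, 2, 1, 2)))
  res0 <- ols_contrast(m0, meta, spec)
  expect_equal(res0$beta[1], 0)
  expect_false(res0$descriptive[1])
})

test_that("beta and p match lm() and the pooled-variance t-test to machine precision", {
  set.seed(42)
  n1 <- 7; n2 <- 9
  meta <- two_group_meta(n1, n2)
  m <- make_scaled(replicate(25, rnorm(n1 + n2, 1, 0.3), simplify = FALSE))
  res <- ols_contrast(m, meta, contrast_spec("bmi_group", "normal", "elevated"))
  for (i in seq_len(nrow(m))) {
    y <- m[i, ]
    x <- as.integer(meta$bmi_group == "elevated")
    fit <- summary(lm(y ~ x))
    expect_equal(res$beta[i], unname(fit$coefficients["x", "Estimate"]), tolerance = 1e-12)
    expect_equal(res$p_raw[i], unname(fit$coefficients["x", "Pr(>|t|)"]), tolerance = 1e-12)
    tt <- t.test(y[x == 1], y[x == 0], var.equal = TRUE)
    expect_equal(res$p_raw[i], tt$p.value, tolerance = 1e-12)
  }
})

test_that("zero residual variance yields p = 1 with a warning, never NaN", {
  meta <- two_group_meta(2, 2)
  m <- make_scaled(list(c(1, 1, 1, 1)))
  expect_warning(res <- ols_contrast(m, meta, contrast_spec("bmi_group", "normal", "elevated")),
                 "zero residual")
  expect_identical(res$p_raw[1], 1)
  expect_false(is.nan(res$p_adj[1]))
})

test_that("BH adjustment equals brute-force step-up on random vectors", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.123), 0.123)
  expect_equal(bh_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(43)
  for (rep in 1:25) {
    p <- runif(sample(1:50, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_bruteforce(p), tolerance = 1e-12)
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-12))   # monotone in rank
    expect_true(all(adj <= 1))
  }
})

test_that("raising the effect threshold never enlarges the descriptive set", {
  set.seed(44)
  n1 <- 10; n2 <- 10
  meta <- two_group_meta(n1, n2)
  m <- make_scaled(replicate(60, rnorm(n1 + n2, 1, 0.4) +
                               sample(c(0, 0.5), 1) * rep(0:1, c(n1, n2)),
                             simplify = FALSE))
  deltas <- c(0.05, 0.2, 0.5, 1)
  sets <- lapply(deltas, function(d) {
    r <- ols_contrast(m, meta, contrast_spec("bmi_group", "normal", "elevated",
                                             coef_threshold = d))
    r$sequence[r$descriptive]
  })
  for (i in seq_along(sets)[-1])
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
})

test_that("summaries count directions per contrast and pool unique panels per condition", {
  res1 <- data.frame(sequence = c("A1", "A2", "A3"), contrast = "sampling_time:3d_vs_1m",
                     condition = "sampling_time", beta = c(1.5, -1.2, 0.1),
                     p_raw = 0.001, p_adj = c(0.01, 0.01, 0.9),
                     direction = c("increased", "decreased", "increased"),
                     descriptive = c(TRUE, TRUE, FALSE))
  res2 <- res1
  res2$contrast <- "sampling_time:3d_vs_2m"
  res2$descriptive <- c(TRUE, FALSE, FALSE)   # A1 descriptive twice
  s <- summarize_contrasts(list(res1, res2))
  expect_identical(s$table$n_increased, c(1L, 1L))
  expect_identical(s$table$n_decreased, c(1L, 0L))
  expect_identical(s$panels$sampling_time, c("A1", "A2"))   # union counts A1 once
  # no descriptive sequences -> zero table, empty panels
  res0 <- res1; res0$descriptive <- FALSE
  s0 <- summarize_contrasts(list(res0))
  expect_identical(s0$table$n_descriptive, 0L)
  expect_length(s0$panels, 0)
})

test_that("planted effects are recovered with the planted direction", {
  cfg <- simulation_config(
    n_ancestors = 200L, n_participants = 40L, timepoints = c("3d", "1m"),
    p_elevated_bmi = 0.5, depth_mean = 5e4, abundance_sigma = 1,
    mutation_rate = 0, seed = 45L,
    planted = list(planted_effect("bmi_group", "elevated", 1:5,
                                  fold_change = 1.8, biological_sigma = 0.2)))
  lib <- generate_library(cfg)
  coh <- generate_cohort(cfg, lib)
  norm <- normalize_counts(coh$counts)
  res <- ols_contrast(norm, coh$metadata, contrast_spec("bmi_group", "normal", "elevated"))
  planted_seqs <- lib$ancestors[1:5]
  hit <- res[res$sequence %in% planted_seqs, ]
  expect_true(all(hit$descriptive))
  expect_true(all(hit$direction == "increased"))
  fdp <- sum(res$descriptive & !(res$sequence %in% planted_seqs)) /
    max(1, sum(res$descriptive))
  expect_lte(fdp, 0.1)
})
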