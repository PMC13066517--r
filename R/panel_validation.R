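#' PCA scores of samples over a descriptive-sequence panel
#'
#' Restricts the scaled matrix to the panel sequences, mean-centers each
#' sequence across samples (no unit-variance scaling: scaled relative-binding
#' values already share the mean-1 scale), and computes principal components
#' by singular value decomposition.  The PC1 sign is fixed deterministically:
#' when `reference`/`study` groups are supplied, PC1 is oriented so the study
#' group's median score is at least the reference group's; otherwise so that
#' the largest-magnitude PC1 loading is positive.
#'
#' @param scaled Scaled matrix (sequences x samples) or `scaled_matrix`
#'   object.
#' @param panel Character vector of panel sequences (>= 2 must be present).
#' @param meta Optional metadata (required for the group sign convention).
#' @param condition,reference,study Optional grouping used only to orient
#'   PC1.
#' @return List with `scores` (samples x components), `explained_variance_ratio`,
#'   `loadings`, `panel_used`, and `panel_coverage` (fraction of panel
#'   sequences present).  Missing panel sequences give a warning; an entirely
#'   absent panel is an error.
#' @export
pca_panel <- function(scaled, panel, meta = NULL, condition = NULL,
                      reference = NULL, study = NULL) {
  if (inherits(scaled, "scaled_matrix")) scaled <- scaled$scaled
  panel <- unique(panel)
  present <- intersect(panel, rownames(scaled))
  if (length(present) == 0) stop("no panel sequences present in the matrix")
  coverage <- length(present) / length(panel)
  if (coverage < 1)
    warning(length(panel) - length(present), " of ", length(panel),
            " panel sequences absent; proceeding with the present subset")
  if (length(present) < 2) stop("need >= 2 panel sequences present")
  if (ncol(scaled) < 3) stop("need >= 3 samples")
  x <- t(scaled[present, , drop = FALSE])   # samples x sequences
  pr <- prcomp(x, center = TRUE, scale. = FALSE)
  evr <- pr$sdev^2 / sum(pr$sdev^2)
  scores <- pr$x
  loadings <- pr$rotation
  flip <- FALSE
  if (!is.null(condition) && !is.null(meta)) {
    col <- condition_column(condition, meta)
    grp <- setNames(meta[[col]], meta$sample_id)[rownames(scores)]
    med_study <- median(scores[grp %in% study, 1])
    med_ref <- median(scores[grp %in% reference, 1])
    flip <- isTRUE(med_study < med_ref)
  } else {
    flip <- loadings[which.max(abs(loadings[, 1])), 1] < 0
  }
  if (flip) { scores[, 1] <- -scores[, 1]; loadings[, 1] <- -loadings[, 1] }
  list(scores = scores, explained_variance_ratio = evr, loadings = loadings,
       panel_used = present, panel_coverage = coverage)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Rank-sum statistic on pooled mid-ranks; the exact null distribution is
#' used when both groups have at most 25 observations and there are no ties,
#' otherwise the normal approximation with tie and continuity corrections.
#'
#' @param x,y Numeric score vectors (both non-empty).
#' @return Two-sided p value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 25 && length(y) <= 25 && !ties
  suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE)$p.value
  )
}

#' Validate a descriptive-sequence panel on an independent cohort
#'
#' Computes PC1 scores of the validation samples over the panel, then
#' per-group medians, unbiased variances and two-sided Wilcoxon rank-sum
#' p values for the configured group pairs.  For `sampling_time` the pairs
#' are each later timepoint against the first plus the second-against-last
#' comparison (1 vs 3 months in the default design); binary conditions give
#' the single reference/study pair.
#'
#' @param scaled Scaled matrix of the validation cohort (scaled with its own
#'   per-sequence means) or `scaled_matrix` object.
#' @param meta Validation metadata.
#' @param panel Character vector of panel sequences frozen from the
#'   discovery cohort.
#' @param grouping `"sampling_time"`, `"bmi_group"` or `"parity"`.
#' @param timepoints Ordered timepoint labels (used when
#'   `grouping = "sampling_time"`).
#' @return Object of class `panel_validation`: list with `grouping`,
#'   `panel`, `panel_coverage`, `scores` (data.frame sample_id, group, pc1),
#'   `explained_variance_ratio`, `group_medians`, `group_variances`
#'   (unbiased, denominator n - 1), and `wilcoxon` (data.frame group1,
#'   group2, p).
#' @export
validate_panel <- function(scaled, meta, panel,
                           grouping = c("sampling_time", "bmi_group", "parity"),
                           timepoints = c("3d", "1m", "2m", "3m")) {
  grouping <- match.arg(grouping)
  if (inherits(scaled, "scaled_matrix")) scaled <- scaled$scaled
  check_samples_match(scaled, meta)
  col <- condition_column(grouping, meta)
  if (grouping == "sampling_time") {
    pairs <- c(lapply(timepoints[-1], function(tp) c(timepoints[1], tp)),
               list(c(timepoints[2], timepoints[length(timepoints)])))
    reference <- timepoints[1]
    study <- timepoints[-1]
  } else {
    lev <- if (grouping == "bmi_group") c("normal", "elevated")
           else c("multiparous", "primiparous")
    pairs <- list(lev)
    reference <- lev[1]
    study <- lev[2]
  }
  grp_all <- setNames(meta[[col]], meta$sample_id)[colnames(scaled)]
  needed <- unique(unlist(pairs))
  absent <- setdiff(needed, grp_all)
  if (length(absent))
    stop("group(s) absent from validation metadata: ", paste(absent, collapse = ", "))
  pca <- pca_panel(scaled, panel, meta = meta, condition = grouping,
                   reference = reference, study = study)
  pc1 <- pca$scores[, 1]
  grp <- grp_all[rownames(pca$scores)]
  medians <- tapply(pc1, grp, median)
  variances <- tapply(pc1, grp, var)   # unbiased, denominator n - 1
  wil <- do.call(rbind, lapply(pairs, function(pr) {
    data.frame(group1 = pr[1], group2 = pr[2],
               p = wilcoxon_rank_sum(pc1[grp == pr[1]], pc1[grp == pr[2]]),
               stringsAsFactors = FALSE)
  }))
  structure(list(
    grouping = grouping, panel = panel, panel_coverage = pca$panel_coverage,
    scores = data.frame(sample_id = rownames(pca$scores), group = unname(grp),
                        pc1 = unname(pc1), stringsAsFactors = FALSE),
    explained_variance_ratio = pca$explained_variance_ratio,
    group_medians = medians, group_variances = variances, wilcoxon = wil
  ), class = "panel_validation")
}

#' @export
print.panel_validation <- function(x, ...) {
  cat("Panel validation (", x$grouping, "): ", length(x$panel),
      " panel sequences, coverage ", sprintf("%.2f", x$panel_coverage), "\n", sep = "")
  cat("PC1 explained variance ratio:",
      sprintf("%.3f", x$explained_variance_ratio[1]), "\n")
  cat("Group medians:\n"); print(round(x$group_medians, 3))
  cat("Group variances (n-1):\n"); print(round(x$group_variances, 3))
  cat("Wilcoxon rank-sum p values:\n"); print(x$wilcoxon)
  invisible(x)
}
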