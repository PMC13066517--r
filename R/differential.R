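#' Specification of a two-group contrast
#'
#' A descriptive sequence for a contrast must pass both a significance
#' threshold (Benjamini-Hochberg adjusted p at most `fdr_q`) and an
#' effect-size threshold (`|beta|` at least `coef_threshold`, in scaled
#' relative-binding units).  By convention the sampling-time contrasts use
#' `coef_threshold = 1` (profound maturation changes are expected), while
#' BMI group and parity use 0.2 to allow a broader discovery-based search of
#' subtler heterogeneous conditions.
#'
#' @param condition `"sampling_time"`, `"bmi_group"`, `"parity"`, or any
#'   metadata column name.
#' @param reference,study Group labels; the fitted coefficient is the mean
#'   scaled-value difference study minus reference.
#' @param coef_threshold Effect-size threshold on `|beta|`; defaults to 1
#'   for `sampling_time` and 0.2 otherwise.
#' @param fdr_q BH false-discovery threshold (default 0.05).
#' @return An object of class `contrast_spec`.
#' @export
contrast_spec <- function(condition, reference, study,
                          coef_threshold = if (condition == "sampling_time") 1 else 0.2,
                          fdr_q = 0.05) {
  stopifnot(coef_threshold > 0, fdr_q > 0, fdr_q < 1)
  structure(list(condition = condition, reference = as.character(reference),
                 study = as.character(study), coef_threshold = coef_threshold,
                 fdr_q = fdr_q,
                 label = paste0(condition, ":", reference, "_vs_", study)),
            class = "contrast_spec")
}

# metadata column backing each condition name
condition_column <- function(condition, meta) {
  col <- c(sampling_time = "timepoint", bmi_group = "bmi_group",
           parity = "parity")[condition]
  if (is.na(col)) col <- condition
  if (!col %in% names(meta)) stop("metadata has no column for condition '", condition, "'")
  unname(col)
}

#' The default contrast set for the longitudinal milk design
#'
#' Each later timepoint against the first (reference) at effect threshold 1,
#' plus BMI group (normal vs elevated) and parity (multiparous vs
#' primiparous) at threshold 0.2.
#'
#' @param timepoints Ordered timepoint labels (first = reference).
#' @param fdr_q BH threshold passed to every contrast.
#' @return List of [contrast_spec()] objects.
#' @export
default_contrasts <- function(timepoints = c("3d", "1m", "2m", "3m"), fdr_q = 0.05) {
  c(
    lapply(timepoints[-1], function(tp)
      contrast_spec("sampling_time", timepoints[1], tp, fdr_q = fdr_q)),
    list(contrast_spec("bmi_group", "normal", "elevated", fdr_q = fdr_q),
         contrast_spec("parity", "multiparous", "primiparous", fdr_q = fdr_q))
  )
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up adjustment; the rejection set at level q is `{p_adj <= q}`.
#'
#' @param p Numeric vector of p values in \\[0, 1\\].
#' @return Adjusted p values (empty input gives empty output).
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Per-sequence OLS contrast on scaled relative-binding values
#'
#' For every sequence, fits `scaled ~ intercept + indicator(study group)` on
#' the union of the reference and study samples only.  With a binary
#' predictor the fitted coefficient equals the group-mean difference and its
#' two-sided p value equals that of the pooled-variance two-sample t test
#' (df = n - 2).  P values are BH-adjusted across all sequences within the
#' contrast; a sequence is descriptive iff `p_adj <= fdr_q` and
#' `|beta| >= coef_threshold`.
#'
#' @param scaled Scaled matrix (sequences x samples) or a `scaled_matrix`
#'   object.
#' @param meta Metadata data.frame covering the matrix's samples.
#' @param spec A [contrast_spec()].
#' @return data.frame with columns `sequence`, `contrast`, `condition`,
#'   `beta`, `p_raw`, `p_adj`, `direction` (`"increased"`/`"decreased"` in
#'   the study group), `descriptive`.
#' @export
ols_contrast <- function(scaled, meta, spec) {
  if (inherits(scaled, "scaled_matrix")) scaled <- scaled$scaled
  stopifnot(inherits(spec, "contrast_spec"))
  check_samples_match(scaled, meta)
  col <- condition_column(spec$condition, meta)
  groups <- setNames(meta[[col]], meta$sample_id)[colnames(scaled)]
  ref_cols <- which(groups == spec$reference)
  study_cols <- which(groups == spec$study)
  if (length(ref_cols) < 2 || length(study_cols) < 2)
    stop("need >= 2 samples in each group for contrast ", spec$label)
  x_ref <- scaled[, ref_cols, drop = FALSE]
  x_study <- scaled[, study_cols, drop = FALSE]
  n1 <- ncol(x_ref); n2 <- ncol(x_study)
  m1 <- rowMeans(x_ref); m2 <- rowMeans(x_study)
  beta <- m2 - m1
  ss <- rowSums((x_ref - m1)^2) + rowSums((x_study - m2)^2)
  df <- n1 + n2 - 2
  s2 <- ss / df
  se <- sqrt(s2 * (1 / n1 + 1 / n2))
  tstat <- beta / se
  p <- 2 * pt(-abs(tstat), df)
  degenerate <- s2 == 0
  if (any(degenerate)) {
    warning(sum(degenerate), " sequence(s) with zero residual variance; p set to 1")
    p[degenerate] <- 1
  }
  p_adj <- bh_adjust(p)
  direction <- ifelse(beta > 0, "increased", ifelse(beta < 0, "decreased", NA))
  data.frame(
    sequence = rownames(scaled), contrast = spec$label, condition = spec$condition,
    beta = beta, p_raw = p, p_adj = p_adj, direction = direction,
    descriptive = p_adj <= spec$fdr_q & abs(beta) >= spec$coef_threshold,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Summarize contrasts and assemble descriptive-sequence panels
#'
#' Per contrast, counts of descriptive sequences increased and decreased in
#' the study group; per condition, the union of unique descriptive sequences
#' across that condition's contrasts (the sampling-time panel pools the
#' per-timepoint comparisons, counting shared sequences once).
#'
#' @param results List of [ols_contrast()] result data.frames.
#' @return List with `table` (data.frame: contrast, condition, n_descriptive,
#'   n_increased, n_decreased) and `panels` (named list: condition ->
#'   character vector of unique descriptive sequences).
#' @export
summarize_contrasts <- function(results) {
  stopifnot(is.list(results), length(results) >= 1)
  tab <- do.call(rbind, lapply(results, function(r) {
    d <- r[r$descriptive, , drop = FALSE]
    data.frame(contrast = r$contrast[1], condition = r$condition[1],
               n_descriptive = nrow(d),
               n_increased = sum(d$direction == "increased"),
               n_decreased = sum(d$direction == "decreased"),
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  all_res <- do.call(rbind, results)
  desc <- all_res[all_res$descriptive, , drop = FALSE]
  panels <- lapply(split(desc$sequence, desc$condition), function(s) sort(unique(s)))
  list(table = tab, panels = panels)
}
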