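#' Log2 relative abundance of pull-down proteins
#'
#' Per pull-down sample, each protein's intensity is expressed as a percent
#' of the sample's total intensity and log2-transformed:
#' `L[p, s] = log2(100 * I[p, s] / sum_p I[p, s])`.  Cells with zero
#' intensity are not detected and are masked (`NA`) in `L`; before the log,
#' per-sample relative abundances sum to 100 over detected proteins.
#'
#' @param intensities Non-negative numeric matrix, proteins x pull-down
#'   samples, with positive column totals.
#' @param top_n How many proteins (by maximum `L` across samples) to flag
#'   for display (default 25).
#' @return Object of class `protein_abundance`: list with `L` (log2 relative
#'   abundance, `NA` where not detected), `relative` (percent scale),
#'   `detected` (logical mask) and `top_proteins` (character, length <=
#'   `top_n`, ordered by descending max `L`).
#' @export
relative_abundance <- function(intensities, top_n = 25L) {
  if (!is.matrix(intensities) || is.null(rownames(intensities)) ||
      is.null(colnames(intensities)))
    stop("intensities must be a matrix with protein row names and sample column names")
  if (any(intensities < 0)) stop("intensities must be non-negative")
  totals <- colSums(intensities)
  bad <- colnames(intensities)[totals == 0]
  if (length(bad)) stop("zero-total sample(s): ", paste(bad, collapse = ", "))
  rel <- sweep(intensities, 2L, totals, "/") * 100
  detected <- intensities > 0
  L <- log2(rel)
  L[!detected] <- NA_real_
  max_l <- apply(L, 1L, function(v) if (all(is.na(v))) -Inf else max(v, na.rm = TRUE))
  ord <- order(-max_l, rownames(intensities))
  top <- rownames(intensities)[head(ord[is.finite(max_l[ord])], top_n)]
  structure(list(L = L, relative = rel, detected = detected,
                 top_proteins = top),
            class = "protein_abundance")
}

#' Classify pull-down proteins as background, model-unique or shared
#'
#' A protein detected in any negative-control pull-down is background
#' (nonspecifically retained or co-purified, like the highly abundant milk
#' proteins seen across all pull-downs including negatives).  A protein
#' detected only in pull-downs of a single model group and in no negative is
#' unique to that group; one detected in two or more groups without negative
#' detection is shared.
#'
#' @param x A `protein_abundance` object or a detection (logical) /
#'   intensity matrix.
#' @param groups Named character vector: sample ID -> model-group label.
#' @param negatives Character vector of negative-control sample IDs.
#' @return Named character vector per protein: `"background"`,
#'   `"unique:<group>"`, `"shared"` or `"not_detected"`.  With no negative
#'   controls the background class is unavailable (warning).
#' @export
flag_unique_proteins <- function(x, groups, negatives = character(0)) {
  detected <- if (inherits(x, "protein_abundance")) x$detected else x > 0
  missing <- setdiff(setdiff(colnames(detected), negatives), names(groups))
  if (length(missing))
    stop("no model group for sample(s): ", paste(missing, collapse = ", "))
  if (length(negatives) == 0)
    warning("no negative controls: classification limited to shared/unique")
  neg_cols <- colnames(detected) %in% negatives
  model_cols <- !neg_cols
  grp <- groups[colnames(detected)[model_cols]]
  vapply(rownames(detected), function(p) {
    det <- detected[p, ]
    if (!any(det)) return("not_detected")
    if (any(det[neg_cols])) return("background")
    g <- unique(grp[det[model_cols]])
    if (length(g) == 1) paste0("unique:", g) else "shared"
  }, character(1))
}

#' Read / write a protein-intensity table with sample model groups
#'
#' TSV whose first line is a comment header `#groups: sample=group ...`
#' naming each sample's model group (`negative` marks negative controls),
#' followed by a `protein` column and one numeric column per sample.
#'
#' @param path File path.
#' @return List with `intensities` (matrix), `groups` (named character) and
#'   `negatives` (character).
#' @export
read_intensities <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#groups:"))
    stop("missing '#groups:' header line")
  assign_str <- strsplit(trimws(sub("^#groups:", "", first)), "[[:space:]]+")[[1]]
  kv <- strsplit(assign_str, "=", fixed = TRUE)
  groups <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  df <- read.delim(path, skip = 1L, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "protein") stop("first column must be 'protein'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$protein
  negatives <- names(groups)[groups == "negative"]
  list(intensities = m, groups = groups[groups != "negative"],
       negatives = negatives)
}

#' @rdname read_intensities
#' @param intensities Protein x sample matrix.
#' @param groups Named character vector sample -> group.
#' @param negatives Negative-control sample IDs.
#' @export
write_intensities <- function(intensities, groups, negatives, path) {
  all_groups <- c(groups, setNames(rep("negative", length(negatives)), negatives))
  all_groups <- all_groups[colnames(intensities)]
  header <- paste0("#groups: ",
                   paste(names(all_groups), all_groups, sep = "=", collapse = " "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  df <- data.frame(protein = rownames(intensities), intensities,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
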