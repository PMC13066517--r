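#' Clustering / filtering configuration
#'
#' Houses the two thresholds applied en route to the final library: sequences
#' within Damerau-Levenshtein distance `d_max` of a more abundant sequence
#' are joined into its family (ancestor proxy), and sequences must then keep
#' at least `c_min` joined reads per sample to be retained.
#'
#' @param d_max Edit-distance threshold for family joining (default 3).
#' @param c_min Minimum reads per sample (default 3).
#' @param presence_mode How the `c_min` rule is applied: `"all_samples"`
#'   (default: required in every sample, minimizing missing values),
#'   `"any_sample"`, or `"mean"` (mean count across samples).
#' @param restricted Use the restricted (OSA) distance variant for joining
#'   instead of the unrestricted metric.
#' @param method `"greedy"` (abundance-anchored assignment, default) or
#'   `"components"` (single-linkage connected components).
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(d_max = 3L, c_min = 3L,
                          presence_mode = c("all_samples", "any_sample", "mean"),
                          restricted = FALSE,
                          method = c("greedy", "components")) {
  stopifnot(d_max >= 0, c_min >= 0)
  structure(list(d_max = as.integer(d_max), c_min = as.integer(c_min),
                 presence_mode = match.arg(presence_mode),
                 restricted = isTRUE(restricted),
                 method = match.arg(method)),
            class = "filter_config")
}

#' Join near-identical sequences into ancestor families
#'
#' Sequences likely arising from the same ancestor (PCR/sequencing
#' derivatives within Damerau-Levenshtein distance `d_max`) are joined.  The
#' default greedy pass visits sequences in descending total count (ties
#' lexicographic); a sequence becomes a new family representative iff no
#' existing representative lies within `d_max`, and otherwise its per-sample
#' counts are added to the nearest representative (ties resolved toward the
#' more abundant, then lexicographically smaller, representative).  A
#' length-difference prefilter (`|len(a) - len(b)| > d_max`) is exact and
#' applied for speed.  Joining moves counts, never drops them, so total
#' reads are conserved, and the result is invariant to input row order.
#'
#' @param m Count matrix.
#' @param cfg A [filter_config()].
#' @return List with `counts` (joined matrix, representatives as rows, in
#'   canonical order) and `families` (data.frame: representative, member,
#'   distance, member_total).
#' @export
join_families <- function(m, cfg = filter_config()) {
  validate_count_matrix(m)
  if (nrow(m) == 0L) stop("empty count matrix")
  m <- order_count_matrix(m)
  seqs <- rownames(m)
  if (cfg$method == "greedy") {
    if (cfg$restricted) {
      res <- greedy_join_r(seqs, cfg$d_max, restricted = TRUE)
    } else {
      res <- .greedy_join_cpp(seqs, cfg$d_max)
    }
    rep_idx <- res$rep
    dist <- res$dist
  } else {
    rep_idx <- components_join(seqs, rowSums(m), cfg$d_max, cfg$restricted)
    dist <- dl_distance(seqs, seqs[rep_idx], restricted = cfg$restricted)
  }
  fam <- data.frame(representative = seqs[rep_idx], member = seqs,
                    distance = dist, member_total = rowSums(m),
                    row.names = NULL, stringsAsFactors = FALSE)
  joined <- rowsum(m, group = rep_idx, reorder = TRUE)
  rownames(joined) <- seqs[as.integer(rownames(joined))]
  storage.mode(joined) <- "integer"
  joined <- order_count_matrix(joined)
  fam <- fam[order(match(fam$representative, rownames(joined)), fam$member), ]
  rownames(fam) <- NULL
  list(counts = joined, families = fam)
}

# Reference greedy pass in R; used for the OSA variant (rare path) and as an
# independent check of the C++ loop in the tests.
greedy_join_r <- function(seqs, d_max, restricted = FALSE) {
  n <- length(seqs)
  rep_idx <- integer(n); dist <- integer(n)
  reps <- integer(0)
  lens <- nchar(seqs)
  for (i in seq_len(n)) {
    best <- d_max + 1L; best_rep <- NA_integer_
    for (j in reps) {
      if (abs(lens[i] - lens[j]) > d_max) next
      d <- dl_distance(seqs[i], seqs[j], restricted = restricted)
      if (d < best) { best <- d; best_rep <- j; if (best == 0L) break }
    }
    if (!is.na(best_rep) && best <= d_max) {
      rep_idx[i] <- best_rep; dist[i] <- best
    } else {
      rep_idx[i] <- i; dist[i] <- 0L; reps <- c(reps, i)
    }
  }
  list(rep = rep_idx, dist = dist)
}

# Single-linkage alternative: connected components of the <= d_max graph;
# representative = highest total count in the component (ties lexicographic).
components_join <- function(seqs, totals, d_max, restricted = FALSE) {
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  lens <- nchar(seqs)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (abs(lens[i] - lens[j]) > d_max) next
      if (restricted) {
        d <- dl_distance(seqs[i], seqs[j], restricted = TRUE)
      } else {
        d <- .dl_capped_many_cpp(seqs[i], seqs[j], as.integer(d_max))
      }
      if (d <= d_max) parent[find(i)] <- find(j)
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  rep_of <- vapply(split(seq_len(n), comp), function(idx) {
    idx[order(-totals[idx], seqs[idx])][1L]
  }, integer(1))
  unname(rep_of[as.character(comp)])
}

#' Apply the minimum-reads-per-sample filter
#'
#' Under the default `all_samples` mode a (joined) sequence is retained iff
#' its count is at least `c_min` in every sample, minimizing bias from
#' missing values due to limited detection sensitivity.
#'
#' @param m Joined count matrix.
#' @param cfg A [filter_config()].
#' @return Filtered count matrix; removed sequences are available in the
#'   `"removed"` attribute and the retained-set size is messaged.
#' @export
filter_min_count <- function(m, cfg = filter_config()) {
  validate_count_matrix(m)
  keep <- switch(cfg$presence_mode,
    all_samples = rowSums(m >= cfg$c_min) == ncol(m),
    any_sample = rowSums(m >= cfg$c_min) > 0L,
    mean = rowMeans(m) >= cfg$c_min
  )
  if (!any(keep))
    stop("min-count filter removed all sequences; review c_min (", cfg$c_min,
         ") and presence_mode ('", cfg$presence_mode, "')")
  out <- m[keep, , drop = FALSE]
  attr(out, "removed") <- rownames(m)[!keep]
  message(sum(keep), " of ", nrow(m), " sequences retained (c_min = ",
          cfg$c_min, ", ", cfg$presence_mode, ")")
  out
}
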