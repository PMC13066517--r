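kmers_of <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  unique(substring(seq, 1:(L - k + 1), k:L))
}

#' k-mer motif enrichment of a descriptive-sequence panel
#'
#' Operationalizes global homology analysis as k-mer containment enrichment:
#' for every k-mer occurring in the panel, the number of panel sequences
#' containing it is compared with its empirical containment frequency in the
#' background library (the full retained sequence set; SELEX libraries are
#' sequence-biased, so an empirical rather than i.i.d.-base background is
#' used) by a one-sided binomial tail test.  Benjamini-Hochberg multiplicity
#' is taken over all `4^k` possible k-mers — the observed k-mers are a
#' selected subset, and adjusting only over them would declare chance
#' singletons enriched.  A k-mer is enriched when `p_adj <= q` and its
#' containment fold over background is at least `min_fold`.
#'
#' @param panel Character vector of panel sequences.
#' @param background Character vector of background library sequences.
#' @param k Motif length (default 7); must not exceed the shortest panel
#'   sequence.
#' @param q BH threshold (default 0.05).
#' @param min_fold Minimum containment fold over background (default 2).
#' @return data.frame (one row per panel k-mer, sorted by `p_adj`, `p_raw`,
#'   motif): `motif`, `count_panel`, `n_panel`, `count_background`,
#'   `n_background`, `fold`, `p_raw`, `p_adj`, `enriched`.
#' @export
motif_enrichment <- function(panel, background, k = 7L, q = 0.05, min_fold = 2) {
  stopifnot(length(panel) >= 1, length(background) >= 1, k >= 1)
  if (k > min(nchar(panel)))
    stop("k (", k, ") exceeds the shortest panel sequence length")
  panel_km <- lapply(panel, kmers_of, k = k)
  motifs <- sort(unique(unlist(panel_km)))
  count_panel <- table(factor(unlist(panel_km), levels = motifs))
  bg_km <- unlist(lapply(background, kmers_of, k = k))
  count_bg <- table(factor(bg_km, levels = motifs))
  n_panel <- length(panel); n_bg <- length(background)
  # pseudocount keeps never-seen-in-background motifs testable
  p0 <- pmax(as.numeric(count_bg), 0.5) / n_bg
  cnt <- as.numeric(count_panel)
  p_raw <- pbinom(cnt - 1, n_panel, p0, lower.tail = FALSE)
  fold <- (cnt / n_panel) / p0
  p_adj <- bh_over_universe(p_raw, m = 4^k)
  df <- data.frame(motif = motifs, count_panel = as.integer(count_panel),
                   n_panel = n_panel, count_background = as.integer(count_bg),
                   n_background = n_bg, fold = fold, p_raw = p_raw,
                   p_adj = p_adj, enriched = p_adj <= q & fold >= min_fold,
                   row.names = NULL, stringsAsFactors = FALSE)
  df[order(df$p_adj, df$p_raw, df$motif), , drop = FALSE]
}

# BH step-up over a hypothesis universe of size m of which only the supplied
# p values were observed (the rest are 1 and can never be rejected).
bh_over_universe <- function(p, m) {
  s <- length(p)
  if (s == 0) return(numeric(0))
  stopifnot(m >= s)
  o <- order(p)
  ranked <- p[o] * m / seq_len(s)
  adj <- rev(cummin(rev(ranked)))      # min over j >= i among observed
  adj <- pmin(adj, 1)                  # the padded p = 1 tail contributes 1
  out <- numeric(s)
  out[o] <- adj
  out
}

#' Build motif-defined candidate-aptamer families
#'
#' Enriched motifs are merged (transitively) when they overlap by `k - 1`
#' characters under a single shift or share at least 50% of their member
#' sequences (relative to the smaller member set).  Each family's members
#' are the panel sequences containing any of its motifs; the representative
#' is the member with the largest summed read count across both cohorts
#' (ties lexicographic), and the family is annotated with every model whose
#' panel contributed a member.  Panel sequences containing no enriched motif
#' are reported as unassigned singletons in the `"unassigned"` attribute.
#'
#' @param motifs Character vector of enriched motifs (e.g. from
#'   [motif_enrichment()]'s `enriched` rows); equal length k-mers.
#' @param panels Named list: model name -> character vector of panel
#'   sequences.
#' @param total_reads Named numeric vector of summed read counts per
#'   sequence over discovery + validation.
#' @return data.frame of class `motif_families`: `family_id`, `motifs`
#'   (`;`-collapsed), `n_members`, `representative`, `models`; member sets in
#'   the `"members"` attribute, unassigned sequences in `"unassigned"`.
#' @export
build_families <- function(motifs, panels, total_reads) {
  stopifnot(is.list(panels), !is.null(names(panels)))
  all_seqs <- sort(unique(unlist(panels)))
  if (length(motifs) == 0) {
    out <- data.frame(family_id = character(0), motifs = character(0),
                      n_members = integer(0), representative = character(0),
                      models = character(0), stringsAsFactors = FALSE)
    attr(out, "members") <- list()
    attr(out, "unassigned") <- all_seqs
    class(out) <- c("motif_families", "data.frame")
    return(out)
  }
  motifs <- sort(unique(motifs))
  k <- unique(nchar(motifs))
  if (length(k) > 1) stop("motifs must have equal length")
  members <- lapply(motifs, function(mo) all_seqs[grepl(mo, all_seqs, fixed = TRUE)])
  # union-find merge
  n <- length(motifs)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    shift <- substr(motifs[i], 2, k) == substr(motifs[j], 1, k - 1) ||
             substr(motifs[j], 2, k) == substr(motifs[i], 1, k - 1)
    ni <- length(members[[i]]); nj <- length(members[[j]])
    share <- if (min(ni, nj) > 0)
      length(intersect(members[[i]], members[[j]])) / min(ni, nj) >= 0.5
    else FALSE
    if (shift || share) parent[find(i)] <- find(j)
  }
  comp <- vapply(seq_len(n), find, integer(1))
  fams <- lapply(split(seq_len(n), comp), function(idx) {
    mem <- sort(unique(unlist(members[idx])))
    list(motifs = motifs[idx], members = mem)
  })
  # deterministic family order: by first motif
  fams <- fams[order(vapply(fams, function(f) f$motifs[1], ""))]
  reads <- function(s) ifelse(is.na(total_reads[s]), 0, total_reads[s])
  rows <- lapply(seq_along(fams), function(i) {
    f <- fams[[i]]
    mem <- f$members
    rep_seq <- if (length(mem)) mem[order(-reads(mem), mem)][1] else NA_character_
    in_model <- vapply(panels, function(p) any(mem %in% p), logical(1))
    data.frame(family_id = sprintf("F%02d", i),
               motifs = paste(f$motifs, collapse = ";"),
               n_members = length(mem), representative = rep_seq,
               models = paste(sort(names(panels)[in_model]), collapse = "+"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "members") <- setNames(lapply(fams, `[[`, "members"), out$family_id)
  covered <- unique(unlist(lapply(fams, `[[`, "members")))
  attr(out, "unassigned") <- setdiff(all_seqs, covered)
  class(out) <- c("motif_families", "data.frame")
  out
}

#' Select representative candidate aptamers per model
#'
#' Ranks families within each model annotation group by representative read
#' count (descending, ties lexicographic on the representative) and emits
#' the top `top_n` representatives with the three selection criteria flags:
#' high read count across both cohorts, conserved family motif, and model
#' representation.
#'
#' @param families A [build_families()] result.
#' @param total_reads Named numeric vector of summed reads per sequence.
#' @param top_n Candidates per model group (single integer, or named vector
#'   keyed by the `models` annotation).
#' @return data.frame: `candidate`, `family_id`, `models`,
#'   `high_read_count`, `conserved_motif`, `model_representation`,
#'   `selected`.  Requesting more candidates than a group has families
#'   returns all with a warning.
#' @export
select_candidates <- function(families, total_reads, top_n = 2L) {
  if (nrow(families) == 0 || all(top_n == 0))
    return(data.frame(candidate = character(0), family_id = character(0),
                      models = character(0), high_read_count = logical(0),
                      conserved_motif = logical(0),
                      model_representation = logical(0), selected = logical(0),
                      stringsAsFactors = FALSE))
  reads <- function(s) ifelse(is.na(total_reads[s]), 0, total_reads[s])
  picks <- lapply(split(seq_len(nrow(families)), families$models), function(idx) {
    grp <- families$models[idx[1]]
    want <- if (length(top_n) == 1 && is.null(names(top_n))) top_n
            else if (grp %in% names(top_n)) top_n[[grp]] else 0L
    if (want == 0L) return(NULL)
    ord <- idx[order(-reads(families$representative[idx]),
                     families$representative[idx])]
    if (want > length(ord)) {
      warning("model group '", grp, "': requested ", want,
              " candidates but only ", length(ord), " families; returning all")
      want <- length(ord)
    }
    head(ord, want)
  })
  idx <- unlist(picks, use.names = FALSE)
  out <- data.frame(candidate = families$representative[idx],
                    family_id = families$family_id[idx],
                    models = families$models[idx],
                    high_read_count = TRUE, conserved_motif = TRUE,
                    model_representation = families$models[idx] != "",
                    stringsAsFactors = FALSE)
  out$selected <- out$high_read_count & out$conserved_motif & out$model_representation
  out <- out[order(out$family_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
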