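#' Simulation configuration for a synthetic branched-selection cohort
#'
#' Defines a longitudinal two-condition milk-profiling study design: an
#' enriched aptamer library of `n_ancestors` true variable-region sequences is
#' presented to one sample per participant per timepoint, reads are drawn
#' multinomially at Poisson depth, and a fraction of reads acquires 1 to
#' `max_edits_per_read` random edits (substitution, insertion, deletion,
#' adjacent transposition), creating the derived-sequence families the
#' clustering stage must undo.
#'
#' Defaults mirror the study design the package targets: 36-nt variable
#' regions, four sampling times (3 days, 1, 2, 3 months; one sample per
#' participant per timepoint), 86 participants with 54/86 in the elevated-BMI
#' group and balanced parity, and a desk-scale mean depth of 1e5 reads per
#' sample.
#'
#' @param n_ancestors Number of true library sequences.
#' @param seq_length Variable-region length in nucleotides.
#' @param n_participants Participants; each contributes one sample per
#'   timepoint.
#' @param timepoints Ordered character vector of sampling-time labels; the
#'   first is the reference level.
#' @param p_elevated_bmi Probability a participant is in the elevated-BMI
#'   (> 25 kg/m^2) group.
#' @param p_primiparous Probability a participant is primiparous.
#' @param depth_mean Mean sequencing depth per sample (Poisson).
#' @param abundance_sigma Log-scale SD of baseline library abundances; 0 gives
#'   a uniform library.
#' @param planted List of [planted_effect()] objects (may be empty: null
#'   simulation).
#' @param mutation_rate Per-read probability of acquiring edit noise.
#' @param max_edits_per_read Maximum edits per mutated read.
#' @param barcode_length Sample barcode length for FASTQ export.
#' @param well_separated If `TRUE`, ancestors are rejection-sampled until all
#'   pairwise Damerau-Levenshtein distances exceed `2 * max_edits_per_read`,
#'   which makes family recovery identifiable.
#' @param balanced If `TRUE`, BMI group and parity are assigned as random
#'   permutations of exactly balanced labels (per `p_elevated_bmi` /
#'   `p_primiparous` rounded to counts) instead of independent coin flips,
#'   fixing the group sizes of a benchmark design.
#' @param seed Integer seed; all downstream randomness derives from it.
#' @return An object of class `simulation_config`.
#' @seealso [generate_library()], [generate_cohort()], [planted_effect()]
#' @export
simulation_config <- function(n_ancestors = 1000L,
                              seq_length = 36L,
                              n_participants = 86L,
                              timepoints = c("3d", "1m", "2m", "3m"),
                              p_elevated_bmi = 54 / 86,
                              p_primiparous = 0.5,
                              depth_mean = 1e5,
                              abundance_sigma = 1.5,
                              planted = list(),
                              mutation_rate = 0.02,
                              max_edits_per_read = 3L,
                              barcode_length = 8L,
                              well_separated = FALSE,
                              balanced = FALSE,
                              seed = 1L) {
  stopifnot(
    n_ancestors >= 1, seq_length >= 1, n_participants >= 1,
    length(timepoints) >= 1, !anyDuplicated(timepoints),
    p_elevated_bmi >= 0, p_elevated_bmi <= 1,
    p_primiparous >= 0, p_primiparous <= 1,
    abundance_sigma >= 0,
    mutation_rate >= 0, mutation_rate <= 1,
    max_edits_per_read >= 1, seq_length >= max_edits_per_read,
    barcode_length >= 1
  )
  if (depth_mean <= 0) stop("depth_mean must be > 0")
  stopifnot(is.list(planted))
  for (e in planted) {
    if (!inherits(e, "planted_effect")) stop("planted must be a list of planted_effect objects")
    if (max(e$sequence_indices) > n_ancestors)
      stop("planted effect references ancestor index beyond n_ancestors")
  }
  # within one condition, effects must target disjoint ancestors
  for (cond in unique(vapply(planted, `[[`, "", "condition"))) {
    idx <- unlist(lapply(planted[vapply(planted, `[[`, "", "condition") == cond],
                         `[[`, "sequence_indices"))
    if (anyDuplicated(idx))
      stop("planted sequence_indices overlap within condition '", cond, "'")
  }
  structure(list(
    n_ancestors = as.integer(n_ancestors), seq_length = as.integer(seq_length),
    n_participants = as.integer(n_participants), timepoints = as.character(timepoints),
    p_elevated_bmi = p_elevated_bmi, p_primiparous = p_primiparous,
    depth_mean = depth_mean, abundance_sigma = abundance_sigma,
    planted = planted, mutation_rate = mutation_rate,
    max_edits_per_read = as.integer(max_edits_per_read),
    barcode_length = as.integer(barcode_length),
    well_separated = isTRUE(well_separated), balanced = isTRUE(balanced),
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Planted condition effect on a set of library sequences
#'
#' A multiplicative fold change `fold_change` on the latent proportion of the
#' chosen ancestors in samples belonging to `study_level` of `condition`,
#' with optional per-sample log-normal biological noise (SD
#' `biological_sigma`, applied to the affected sequences in every sample).
#' Effects are applied before compositional renormalization, matching the
#' percent-of-total normalization used downstream.
#'
#' @param condition One of `"sampling_time"`, `"bmi_group"`, `"parity"`.
#' @param study_level Group label carrying the effect (e.g. `"1m"`,
#'   `"elevated"`, `"primiparous"`).
#' @param sequence_indices Ancestor indices carrying the effect.
#' @param fold_change Multiplicative effect (> 0) on latent proportion.
#' @param biological_sigma Log-normal per-sample noise SD on the affected
#'   sequences.
#' @return An object of class `planted_effect`.
#' @export
planted_effect <- function(condition, study_level, sequence_indices,
                           fold_change = 1.5, biological_sigma = 0.3) {
  condition <- match.arg(condition, c("sampling_time", "bmi_group", "parity"))
  stopifnot(fold_change > 0, biological_sigma >= 0, length(sequence_indices) >= 1)
  structure(list(condition = condition, study_level = as.character(study_level),
                 sequence_indices = as.integer(sequence_indices),
                 fold_change = fold_change, biological_sigma = biological_sigma),
            class = "planted_effect")
}

random_sequences <- function(n, len, alphabet = c("A", "C", "G", "U")) {
  chars <- sample(alphabet, n * len, replace = TRUE)
  apply(matrix(chars, nrow = n), 1L, paste, collapse = "")
}

#' Generate the enriched aptamer library
#'
#' Draws `n_ancestors` distinct random variable-region sequences over the RNA
#' alphabet and baseline library proportions as normalized
#' `exp(Normal(0, abundance_sigma))`.  With `well_separated`, sequences are
#' accepted one at a time only if their unrestricted Damerau-Levenshtein
#' distance to every accepted sequence exceeds `2 * max_edits_per_read`;
#' a bounded number of rejections signals an infeasible separation request.
#'
#' @param config A [simulation_config()].
#' @param max_attempts Total candidate draws allowed during rejection
#'   sampling.
#' @return List with `ancestors` (character) and `baseline_proportions`
#'   (numeric summing to 1).
#' @export
generate_library <- function(config, max_attempts = 1000L * config$n_ancestors) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_ancestors
  sep <- 2L * config$max_edits_per_read
  if (!config$well_separated) {
    anc <- random_sequences(n, config$seq_length)
    attempts <- 0L
    while (anyDuplicated(anc) && attempts < 100L) {
      dup <- duplicated(anc)
      anc[dup] <- random_sequences(sum(dup), config$seq_length)
      attempts <- attempts + 1L
    }
    if (anyDuplicated(anc))
      stop("could not draw distinct ancestors; sequence space too small")
  } else {
    anc <- character(0)
    attempts <- 0L
    while (length(anc) < n) {
      cand <- random_sequences(1L, config$seq_length)
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop("rejection sampling failed: cannot place ", n,
             " ancestors of length ", config$seq_length,
             " with pairwise distance > ", sep)
      if (length(anc) == 0L || .min_dist_capped_cpp(cand, anc, sep) > sep)
        anc <- c(anc, cand)
    }
  }
  raw <- if (config$abundance_sigma == 0) rep(1, n) else
    exp(rnorm(n, 0, config$abundance_sigma))
  list(ancestors = anc, baseline_proportions = raw / sum(raw))
}

# Apply n_edits random single-character edits to a character vector of bases.
mutate_chars <- function(chars, n_edits, alphabet = c("A", "C", "G", "U")) {
  for (k in seq_len(n_edits)) {
    L <- length(chars)
    op <- sample.int(4L, 1L)
    if (op == 1L) {                       # substitution to a different base
      pos <- sample.int(L, 1L)
      chars[pos] <- sample(setdiff(alphabet, chars[pos]), 1L)
    } else if (op == 2L) {                # insertion
      pos <- sample.int(L + 1L, 1L)
      chars <- append(chars, sample(alphabet, 1L), after = pos - 1L)
    } else if (op == 3L) {                # deletion
      if (L > 1L) chars <- chars[-sample.int(L, 1L)]
    } else {                              # adjacent transposition
      if (L > 1L) {
        pos <- sample.int(L - 1L, 1L)
        chars[c(pos, pos + 1L)] <- chars[c(pos + 1L, pos)]
      }
    }
  }
  chars
}

#' Generate a synthetic cohort of aptamer-library read counts
#'
#' For each sample, latent proportions are the baseline library proportions
#' times the fold changes of every planted effect whose study group contains
#' the sample, times per-sample log-normal biological noise on affected
#' sequences, renormalized to sum to 1 (compositional closure).  Read counts
#' are Multinomial at Poisson(`depth_mean`) depth; each read is then mutated
#' with probability `mutation_rate` by 1..`max_edits_per_read` uniform edits,
#' so observed counts spread over derived sequences within edit distance
#' `max_edits_per_read` of their ancestor.
#'
#' @param config A [simulation_config()].
#' @param library Optional result of [generate_library()]; generated (from
#'   `config$seed`) when `NULL`.
#' @param cohort `"discovery"` or `"validation"`; controls sample/participant
#'   ID prefixes so the two cohorts are disjoint.
#' @param seed Seed for the cohort draw (defaults to `config$seed + 1` so the
#'   library and cohort draws are independent but both reproducible).
#' @return List with `counts` (integer matrix, sequences x samples, in
#'   canonical order), `metadata` (data.frame: sample_id, participant_id,
#'   timepoint, bmi_group, parity, cohort) and `truth` (ancestors, baseline
#'   and per-sample latent proportions, planted effects, derived-to-ancestor
#'   map).
#' @export
generate_cohort <- function(config, library = NULL,
                            cohort = c("discovery", "validation"),
                            seed = config$seed + 1L) {
  stopifnot(inherits(config, "simulation_config"))
  cohort <- match.arg(cohort)
  if (is.null(library)) library <- generate_library(config)
  anc <- library$ancestors
  base <- library$baseline_proportions
  n_anc <- length(anc)
  set.seed(seed)

  prefix <- if (cohort == "discovery") "D" else "V"
  np <- config$n_participants
  participants <- sprintf("%sP%03d", prefix, seq_len(np))
  if (config$balanced) {
    n_elev <- round(np * config$p_elevated_bmi)
    bmi <- sample(rep(c("elevated", "normal"), c(n_elev, np - n_elev)))
    n_prim <- round(np * config$p_primiparous)
    parity <- sample(rep(c("primiparous", "multiparous"), c(n_prim, np - n_prim)))
  } else {
    bmi <- ifelse(stats::runif(np) < config$p_elevated_bmi, "elevated", "normal")
    parity <- ifelse(stats::runif(np) < config$p_primiparous, "primiparous", "multiparous")
  }
  meta <- data.frame(
    sample_id = paste0(rep(participants, each = length(config$timepoints)), "_",
                       rep(config$timepoints, np)),
    participant_id = rep(participants, each = length(config$timepoints)),
    timepoint = rep(config$timepoints, np),
    bmi_group = rep(bmi, each = length(config$timepoints)),
    parity = rep(parity, each = length(config$timepoints)),
    cohort = cohort,
    stringsAsFactors = FALSE
  )
  ns <- nrow(meta)

  # latent proportions: baseline x planted folds x biological noise, closed
  latent <- matrix(rep(base, ns), nrow = n_anc, ncol = ns,
                   dimnames = list(NULL, meta$sample_id))
  cond_col <- c(sampling_time = "timepoint", bmi_group = "bmi_group", parity = "parity")
  for (e in config$planted) {
    in_study <- meta[[cond_col[[e$condition]]]] == e$study_level
    if (!any(in_study))
      stop("planted effect study level '", e$study_level, "' absent from metadata")
    latent[e$sequence_indices, in_study] <-
      latent[e$sequence_indices, in_study] * e$fold_change
    if (e$biological_sigma > 0) {
      noise <- matrix(exp(rnorm(length(e$sequence_indices) * ns, 0, e$biological_sigma)),
                      nrow = length(e$sequence_indices))
      latent[e$sequence_indices, ] <- latent[e$sequence_indices, ] * noise
    }
  }
  latent <- sweep(latent, 2L, colSums(latent), "/")

  depth <- rpois(ns, config$depth_mean)
  counts <- matrix(0L, nrow = n_anc, ncol = ns, dimnames = list(anc, meta$sample_id))
  for (i in seq_len(ns))
    counts[, i] <- rmultinom(1L, depth[i], latent[, i])[, 1L]
  pre_mutation <- counts

  derived_map <- character(0)
  if (config$mutation_rate > 0) {
    anc_chars <- strsplit(anc, "", fixed = TRUE)
    extra <- list()  # accumulated derived read keys "sample\tsequence"
    for (i in seq_len(ns)) {
      n_mut <- rbinom(n_anc, counts[, i], config$mutation_rate)
      hit <- which(n_mut > 0L)
      if (!length(hit)) next
      counts[hit, i] <- counts[hit, i] - n_mut[hit]
      reads_anc <- rep(hit, n_mut[hit])
      edits <- sample.int(config$max_edits_per_read, length(reads_anc), replace = TRUE)
      out <- character(length(reads_anc))
      for (r in seq_along(reads_anc))
        out[r] <- paste(mutate_chars(anc_chars[[reads_anc[r]]], edits[r]), collapse = "")
      new_map <- !(out %in% anc) & !(out %in% names(derived_map))
      if (any(new_map)) {
        m <- setNames(anc[reads_anc[new_map]], out[new_map])
        derived_map <- c(derived_map, m[!duplicated(names(m))])
      }
      extra[[length(extra) + 1L]] <- data.frame(sample = i, seq = out)
    }
    if (length(extra)) {
      ex <- do.call(rbind, extra)
      # mutated reads landing on an ancestor string go back to that row
      on_anc <- ex$seq %in% anc
      if (any(on_anc)) {
        tab <- table(factor(ex$seq[on_anc], levels = anc), ex$sample[on_anc])
        counts[, as.integer(colnames(tab))] <-
          counts[, as.integer(colnames(tab))] + unclass(tab)
      }
      ex <- ex[!on_anc, , drop = FALSE]
      if (nrow(ex)) {
        dseq <- sort(unique(ex$seq))
        tab <- table(factor(ex$seq, levels = dseq), factor(ex$sample, levels = seq_len(ns)))
        dmat <- matrix(as.integer(tab), nrow = length(dseq),
                       dimnames = list(dseq, meta$sample_id))
        counts <- rbind(counts, dmat)
      }
    }
  }
  storage.mode(counts) <- "integer"
  counts <- order_count_matrix(counts)

  truth <- list(ancestors = anc, baseline_proportions = base,
                latent = latent, planted = config$planted,
                pre_mutation_counts = pre_mutation,
                derived_map = derived_map)
  list(counts = counts, metadata = meta, truth = truth)
}
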