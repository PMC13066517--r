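#' @name library_io
#' @title Count-matrix, metadata, FASTA and FASTQ input/output
#' @description
#' The pipeline's central object is the count matrix: a non-negative integer
#' matrix with unique variable-region sequences as row names and sample IDs
#' as column names.  All writers emit rows in canonical order (descending
#' total count, ties lexicographic), so I/O is deterministic and
#' order-stable.
NULL

# canonical row order: descending total count, ties lexicographic
order_count_matrix <- function(m) {
  m[order(-rowSums(m), rownames(m)), , drop = FALSE]
}

validate_count_matrix <- function(m) {
  if (!is.matrix(m) || is.null(rownames(m)) || is.null(colnames(m)))
    stop("count matrix must have sequence row names and sample column names")
  if (anyDuplicated(rownames(m))) stop("duplicate sequence rows")
  if (anyDuplicated(colnames(m))) stop("duplicate sample columns")
  if (any(m < 0)) stop("counts must be non-negative")
  invisible(m)
}

#' Read / write a sequence-by-sample count table
#'
#' TSV with first column `sequence`, one column per sample, integer cells.
#' `write_counts` followed by `read_counts` is the identity on valid
#' matrices (up to canonical row order).  Sequences are stored uppercase on
#' the RNA alphabet (`T` is normalized to `U`).
#'
#' @param path File path.
#' @param m Count matrix (sequences x samples).
#' @return `read_counts`: integer count matrix in canonical order.
#' @export
read_counts <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "sequence") stop("first column must be 'sequence'")
  seqs <- norm_rna(df$sequence)
  if (anyDuplicated(seqs)) stop("duplicate sequence rows in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- seqs
  validate_count_matrix(m)
  order_count_matrix(m)
}

#' @rdname read_counts
#' @export
write_counts <- function(m, path) {
  validate_count_matrix(m)
  m <- order_count_matrix(m)
  df <- data.frame(sequence = rownames(m), m, check.names = FALSE,
                   row.names = NULL, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the sample metadata table
#'
#' TSV with columns `sample_id`, `participant_id`, `timepoint`, `bmi_group`,
#' `parity`, `cohort` (extra covariate columns are carried through).
#'
#' @param path File path.
#' @param meta Metadata data.frame.
#' @return `read_metadata`: data.frame.
#' @export
read_metadata <- function(path) {
  meta <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("sample_id", "participant_id", "timepoint", "bmi_group",
                "parity", "cohort")
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop("metadata missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata")
  meta
}

#' @rdname read_metadata
#' @export
write_metadata <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check that a count matrix and metadata describe the same samples
#'
#' Hard check used before any joint analysis; errors list the offending
#' sample IDs.
#'
#' @param m Count matrix.
#' @param meta Metadata data.frame.
#' @return Invisibly `TRUE`.
#' @export
check_samples_match <- function(m, meta) {
  in_counts <- setdiff(colnames(m), meta$sample_id)
  in_meta <- setdiff(meta$sample_id, colnames(m))
  if (length(in_counts))
    stop("samples in counts missing from metadata: ",
         paste(in_counts, collapse = ", "))
  if (length(in_meta))
    stop("samples in metadata missing from counts: ",
         paste(in_meta, collapse = ", "))
  invisible(TRUE)
}

#' Export a sequence panel as FASTA
#'
#' Sequences are written in stable lexicographic order with IDs
#' `panel_0001`, `panel_0002`, ...
#'
#' @param sequences Character vector of sequences.
#' @param path Output path.
#' @return Invisibly the path.
#' @export
write_panel_fasta <- function(sequences, path) {
  sequences <- sort(unique(norm_rna(sequences)))
  lines <- character(2L * length(sequences))
  lines[c(TRUE, FALSE)] <- sprintf(">panel_%04d", seq_along(sequences))
  lines[c(FALSE, TRUE)] <- sequences
  writeLines(lines, path)
  invisible(path)
}

#' Write barcoded amplicon reads as FASTQ
#'
#' Emits one record per read: `barcode + flank5 + variable region + flank3`
#' on the DNA alphabet with constant dummy qualities, `counts[s, i]` records
#' for sequence `s` in sample `i`.  Round-trips through [demultiplex()] to
#' the identical count matrix.
#'
#' @param m Count matrix (variable regions x samples).
#' @param barcodes Named character vector, one barcode per sample
#'   (names = sample IDs); must be unique and equal length.
#' @param flank5,flank3 Constant flanking sequences (may be `""`).
#' @param path Output FASTQ path.
#' @return Invisibly the number of records written.
#' @export
write_fastq <- function(m, barcodes, flank5, flank3, path) {
  validate_count_matrix(m)
  if (anyDuplicated(barcodes)) stop("duplicate barcodes")
  if (length(unique(nchar(barcodes))) > 1) stop("barcodes must have equal length")
  missing <- setdiff(colnames(m), names(barcodes))
  if (length(missing)) stop("no barcode for sample(s): ", paste(missing, collapse = ", "))
  con <- file(path, "w")
  on.exit(close(con))
  n_total <- 0L
  for (s in colnames(m)) {
    cnt <- m[, s]
    keep <- cnt > 0L
    if (!any(keep)) next
    reads <- rep(rownames(m)[keep], cnt[keep])
    full <- rna_to_dna(paste0(barcodes[[s]], flank5, reads, flank3))
    recs <- character(4L * length(full))
    recs[c(TRUE, FALSE, FALSE, FALSE)] <- sprintf("@read_%07d", n_total + seq_along(full))
    recs[c(FALSE, TRUE, FALSE, FALSE)] <- full
    recs[c(FALSE, FALSE, TRUE, FALSE)] <- "+"
    recs[c(FALSE, FALSE, FALSE, TRUE)] <- strrep("I", nchar(full))
    writeLines(recs, con)
    n_total <- n_total + length(full)
  }
  invisible(n_total)
}

#' Demultiplex barcoded FASTQ into a count matrix
#'
#' Reads are assigned to samples by barcode prefix match (exact by default;
#' `max_mismatch = 1` allows one mismatch, with ambiguity sending the read to
#' the unassigned bucket).  The constant flanks are then stripped by exact
#' prefix/suffix match; reads failing the structure go to the unassigned
#' bucket.  Assigned + unassigned always equals the number of records.
#'
#' @param path FASTQ file.
#' @param barcodes Named character vector (names = sample IDs), unique, equal
#'   length.
#' @param flank5,flank3 Constant flanks as literal strings.
#' @param max_mismatch Allowed barcode mismatches (0 or 1).
#' @return List with `counts` (count matrix over all barcode samples, zero
#'   columns kept), `n_assigned`, `n_unassigned`, `n_total`.
#' @export
demultiplex <- function(path, barcodes, flank5 = "", flank3 = "",
                        max_mismatch = 0L) {
  if (anyDuplicated(barcodes)) stop("duplicate barcodes")
  if (length(unique(nchar(barcodes))) > 1) stop("barcodes must have equal length")
  stopifnot(max_mismatch %in% c(0L, 1L))
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stop("malformed FASTQ: record count not a multiple of 4")
  reads <- norm_rna(lines[c(FALSE, TRUE, FALSE, FALSE)])
  n_total <- length(reads)
  bl <- unique(nchar(barcodes))
  bc_rna <- norm_rna(unname(barcodes))
  obs_bc <- substr(reads, 1L, bl)
  if (max_mismatch == 0L) {
    assign_idx <- match(obs_bc, bc_rna)
  } else {
    mm <- matrix(0L, nrow = n_total, ncol = length(bc_rna))
    for (k in seq_len(bl)) {
      ch <- substr(obs_bc, k, k)
      for (b in seq_along(bc_rna))
        mm[, b] <- mm[, b] + (ch != substr(bc_rna[b], k, k))
    }
    best <- apply(mm, 1L, min)
    n_best <- rowSums(mm == best)
    assign_idx <- ifelse(best <= max_mismatch & n_best == 1L,
                         max.col(-mm, ties.method = "first"), NA_integer_)
  }
  rest <- substring(reads, bl + 1L)
  f5 <- norm_rna(flank5); f3 <- norm_rna(flank3)
  ok <- !is.na(assign_idx) &
    nchar(rest) >= nchar(f5) + nchar(f3) &
    (nchar(f5) == 0L | startsWith(rest, f5)) &
    (nchar(f3) == 0L | endsWith(rest, f3))
  var_region <- substr(rest, nchar(f5) + 1L, nchar(rest) - nchar(f3))
  ok <- ok & nchar(var_region) > 0L
  n_assigned <- sum(ok)
  if (n_assigned == 0L) {
    warning("no reads assigned during demultiplexing")
    counts <- matrix(integer(0), nrow = 0, ncol = length(barcodes),
                     dimnames = list(NULL, names(barcodes)))
  } else {
    seqs <- sort(unique(var_region[ok]))
    tab <- table(factor(var_region[ok], levels = seqs),
                 factor(names(barcodes)[assign_idx[ok]], levels = names(barcodes)))
    counts <- matrix(as.integer(tab), nrow = length(seqs),
                     dimnames = list(seqs, names(barcodes)))
    counts <- order_count_matrix(counts)
  }
  list(counts = counts, n_assigned = n_assigned,
       n_unassigned = n_total - n_assigned, n_total = n_total)
}
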