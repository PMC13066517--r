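#' Damerau-Levenshtein distance between sequences
#'
#' Minimum number of single-character substitutions, insertions, deletions and
#' adjacent transpositions converting one string into the other.  The default
#' is the unrestricted metric (Lowrance-Wagner), under which a transposed pair
#' may be edited again; `restricted = TRUE` gives the optimal string alignment
#' (OSA) variant, which forbids that and is what several common
#' implementations compute.  The two differ on cases such as
#' `dl_distance("CA", "ABC")`: 2 unrestricted, 3 restricted.
#'
#' The unrestricted variant is a true metric (symmetry, identity of
#' indiscernibles, triangle inequality); OSA violates the triangle inequality.
#'
#' @param a,b Character vectors of sequences (recycled to common length).
#'   Empty strings are valid; the distance to an empty string is the other
#'   string's length.
#' @param restricted Logical; compute the restricted (OSA) variant instead of
#'   the unrestricted metric.
#' @return Integer vector of distances.
#' @examples
#' dl_distance("ACGU", "ACGU")   # 0
#' dl_distance("CA", "AC")       # 1 (one adjacent transposition)
#' dl_distance("CA", "ABC")      # 2
#' dl_distance("CA", "ABC", restricted = TRUE)  # 3
#' @export
dl_distance <- function(a, b, restricted = FALSE) {
  a <- as.character(a)
  b <- as.character(b)
  n <- max(length(a), length(b))
  if (length(a) == 0L || length(b) == 0L) return(integer(0))
  if (length(a) != n) a <- rep_len(a, n)
  if (length(b) != n) b <- rep_len(b, n)
  if (anyNA(a) || anyNA(b)) stop("sequences must not be NA")
  .dl_distance_cpp(a, b, isTRUE(restricted))
}

# Normalize a nucleotide sequence: uppercase, DNA thymine -> RNA uracil.
# The package works on the RNA alphabet internally; conversion is lossless.
norm_rna <- function(x) chartr("Tt", "Uu", toupper(x))

# RNA -> DNA for FASTQ/FASTA export.
rna_to_dna <- function(x) chartr("U", "T", toupper(x))
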