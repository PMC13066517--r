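# Independent oracles used across the suite.  These deliberately use
# different algorithms (and different code paths) from the implementation.

# Exhaustive breadth-first search over single-edit moves: the definitional
# unrestricted Damerau-Levenshtein distance (any edit may be applied to the
# current string at any time, including inside previously transposed pairs).
# Feasible for short strings only.
bfs_dl_oracle <- function(a, b) {
  alphabet <- unique(c(strsplit(paste0(a, b), "")[[1]]))
  if (length(alphabet) == 0) return(0L)
  if (identical(a, b)) return(0L)
  frontier <- a
  seen <- new.env(hash = TRUE)
  key <- function(x) paste0("k", x)  # "" is not a valid environment name
  assign(key(a), TRUE, envir = seen)
  depth <- 0L
  repeat {
    depth <- depth + 1L
    nxt <- character(0)
    for (s in frontier) {
      ch <- if (nchar(s)) strsplit(s, "")[[1]] else character(0)
      L <- length(ch)
      cand <- character(0)
      for (i in seq_len(L)) for (x in alphabet)
        if (x != ch[i]) cand <- c(cand, paste(replace(ch, i, x), collapse = ""))
      for (i in 0:L) for (x in alphabet)
        cand <- c(cand, paste(append(ch, x, after = i), collapse = ""))
      if (L > 0) for (i in seq_len(L))
        cand <- c(cand, paste(ch[-i], collapse = ""))
      if (L > 1) for (i in seq_len(L - 1)) {
        sw <- ch; sw[c(i, i + 1)] <- sw[c(i + 1, i)]
        cand <- c(cand, paste(sw, collapse = ""))
      }
      for (x in unique(cand)) {
        if (x == b) return(depth)
        # prune: never useful to grow much longer than the target
        if (nchar(x) > nchar(b) + 2) next
        if (!exists(key(x), envir = seen, inherits = FALSE)) {
          assign(key(x), TRUE, envir = seen)
          nxt <- c(nxt, x)
        }
      }
    }
    frontier <- nxt
    if (length(frontier) == 0 || depth > nchar(a) + nchar(b)) stop("BFS failed")
  }
}

# Top-down memoized transcription of the published unrestricted recurrence
# (last-occurrence bookkeeping), independent of the C++ bottom-up loop.
recursive_dl_oracle <- function(a, b) {
  av <- if (nchar(a)) strsplit(a, "")[[1]] else character(0)
  bv <- if (nchar(b)) strsplit(b, "")[[1]] else character(0)
  m <- length(av); n <- length(bv)
  INF <- m + n
  memo <- array(NA_integer_, dim = c(m + 2, n + 2))
  h <- function(i, j) {   # i, j in -1..m / -1..n ; offset by 2 for indexing
    if (i == -1L || j == -1L) return(INF)
    if (!is.na(memo[i + 2, j + 2])) return(memo[i + 2, j + 2])
    val <- if (i == 0L) j else if (j == 0L) i else {
      cost <- if (av[i] == bv[j]) 0L else 1L
      best <- min(h(i - 1L, j - 1L) + cost, h(i, j - 1L) + 1L, h(i - 1L, j) + 1L)
      k <- max(c(0L, which(av[seq_len(i - 1L)] == bv[j])))
      l <- max(c(0L, which(bv[seq_len(j - 1L)] == av[i])))
      if (k > 0L && l > 0L)
        best <- min(best, h(k - 1L, l - 1L) + (i - k - 1L) + 1L + (j - l - 1L))
      best
    }
    memo[i + 2, j + 2] <<- val
    val
  }
  h(m, n)
}

# Plain recursive OSA definition (memoized): transposition term only when the
# two final pairs cross, with no re-editing.
recursive_osa_oracle <- function(a, b) {
  av <- if (nchar(a)) strsplit(a, "")[[1]] else character(0)
  bv <- if (nchar(b)) strsplit(b, "")[[1]] else character(0)
  m <- length(av); n <- length(bv)
  memo <- array(NA_integer_, dim = c(m + 1, n + 1))
  d <- function(i, j) {
    if (i == 0L) return(j)
    if (j == 0L) return(i)
    if (!is.na(memo[i + 1, j + 1])) return(memo[i + 1, j + 1])
    cost <- if (av[i] == bv[j]) 0L else 1L
    val <- min(d(i - 1L, j) + 1L, d(i, j - 1L) + 1L, d(i - 1L, j - 1L) + cost)
    if (i > 1L && j > 1L && av[i] == bv[j - 1L] && av[i - 1L] == bv[j])
      val <- min(val, d(i - 2L, j - 2L) + 1L)
    memo[i + 1, j + 1] <<- val
    val
  }
  d(m, n)
}

# Brute-force Benjamini-Hochberg step-up: adjusted_i = min_{j >= rank(i)}
# m * p_(j) / j, capped at 1.
bh_bruteforce <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  sorted <- p[o]
  adj <- vapply(seq_len(m), function(i)
    min(1, min(m * sorted[i:m] / (i:m))), numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

random_rna <- function(n, len, alphabet = c("A", "C", "G", "U")) {
  vapply(seq_len(n), function(i)
    paste(sample(alphabet, len, replace = TRUE), collapse = ""), character(1))
}

# small deterministic count matrix fixture
toy_counts <- function() {
  m <- matrix(c(25L, 75L, 10L,
                40L, 10L, 30L,
                30L, 10L, 50L,
                 5L,  5L, 10L), nrow = 4, byrow = TRUE,
              dimnames = list(c("ACGU", "CCCC", "GGGG", "UUUU"),
                              c("s1", "s2", "s3")))
  m
}
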