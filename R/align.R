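# Codon-aware alignment: sequences are handled as vectors of codons, so
# gaps always come in multiples of 3 nucleotides.  Scoring is nucleotide
# match 2 / mismatch -1 summed per codon, affine codon gaps (open -5,
# -3 per gapped codon).

GAP_CODON <- "---"

codon_pair_score <- function(a, b) {
  if (a == GAP_CODON && b == GAP_CODON) return(0)
  if (a == GAP_CODON || b == GAP_CODON) return(-3)
  s <- 0
  for (k in 1:3) s <- s + if (substr(a, k, k) == substr(b, k, k)) 2 else -1
  s
}

.pair_env <- new.env(parent = emptyenv())

codon_pair_score_memo <- function(a, b) {
  key <- paste0(a, b)
  v <- .pair_env[[key]]
  if (is.null(v)) {
    v <- codon_pair_score(a, b)
    .pair_env[[key]] <- v
  }
  v
}

#' Global codon-aware pairwise alignment
#'
#' Needleman-Wunsch on codon units with affine gaps (nucleotide match 2,
#' mismatch -1; codon gap open -5, extend -3 = three single-base
#' extensions), so indels always span whole codons.
#'
#' @param a,b coding sequences (character; length multiple of 3).
#' @return List with `a`, `b`: aligned codon vectors (gap codon `"---"`),
#'   and `score`.
#' @export
nw_codons <- function(a, b) {
  ca <- split_codons(a); cb <- split_codons(b)
  n <- length(ca); m <- length(cb)
  if (n == 0L || m == 0L) stop("cannot align empty sequence")
  go <- -5; ge <- -3
  NEG <- -1e9
  # codon-codon scores: 3 * (matching positions) - 3, via vectorized
  # position comparison
  S <- matrix(-3, n, m)
  for (k in 1:3) {
    S <- S + 3 * outer(substr(ca, k, k), substr(cb, k, k), "==")
  }
  M <- matrix(NEG, n + 1L, m + 1L)   # match/mismatch state
  X <- matrix(NEG, n + 1L, m + 1L)   # gap in b (a consumed)
  Y <- matrix(NEG, n + 1L, m + 1L)   # gap in a
  M[1, 1] <- 0
  X[-1L, 1L] <- go + ge * seq_len(n)
  Y[1L, -1L] <- go + ge * seq_len(m)
  cols <- seq_len(m)
  for (i in seq_len(n)) {
    best_prev <- pmax(M[i, ], X[i, ], Y[i, ])
    M[i + 1L, -1L] <- best_prev[cols] + S[i, ]
    X[i + 1L, -1L] <- pmax(M[i, -1L] + go + ge, X[i, -1L] + ge)
    # Y depends on the current row left-to-right; solve with cummax:
    # Y[i+1, c] = ge*c + go + max_{t < c} (M[i+1, t] - ge*t)
    mrow <- c(M[i + 1L, 1L], M[i + 1L, -1L])[cols]  # M[i+1, 0..m-1]
    Y[i + 1L, -1L] <- ge * cols + go + cummax(mrow - ge * (cols - 1L))
  }
  # traceback (prefer M, then X, then Y for determinism)
  i <- n; j <- m
  st <- which.max(c(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L]))
  score <- c(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])[st]
  out_a <- character(0); out_b <- character(0)
  while (i > 0L || j > 0L) {
    if (st == 1L) {
      prev <- c(M[i, j], X[i, j], Y[i, j])
      out_a <- c(ca[i], out_a); out_b <- c(cb[j], out_b)
      i <- i - 1L; j <- j - 1L
      st <- which.max(prev)
    } else if (st == 2L) {
      out_a <- c(ca[i], out_a); out_b <- c(GAP_CODON, out_b)
      st <- if (i > 1L && abs(X[i + 1L, j + 1L] - (X[i, j + 1L] - 3)) < 1e-9) 2L else 1L
      if (j == 0L) st <- 2L
      i <- i - 1L
    } else {
      out_a <- c(GAP_CODON, out_a); out_b <- c(cb[j], out_b)
      st <- if (j > 1L && abs(Y[i + 1L, j + 1L] - (Y[i + 1L, j] - 3)) < 1e-9) 3L else 1L
      if (i == 0L) st <- 3L
      j <- j - 1L
    }
    if (i == 0L && j > 0L) st <- 3L
    if (j == 0L && i > 0L) st <- 2L
  }
  list(a = out_a, b = out_b, score = score)
}

#' Pairwise identity of two coding sequences
#'
#' Identity = identical nucleotide positions / alignment length, computed on
#' the codon-aware global alignment; terminal gap columns are excluded from
#' the denominator, internal gaps included.
#'
#' @param a,b coding sequences.
#' @return Numeric scalar in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  if (identical(a, b)) return(1)
  al <- nw_codons(a, b)
  ga <- al$a == GAP_CODON
  gb <- al$b == GAP_CODON
  both <- !(ga | gb)
  # terminal gap columns
  nonterm <- seq_along(ga) >= min(which(both)) & seq_along(ga) <= max(which(both))
  ident <- 0L; total <- 0L
  for (k in which(nonterm)) {
    if (ga[k] || gb[k]) { total <- total + 3L; next }
    xa <- strsplit(al$a[k], "")[[1]]; xb <- strsplit(al$b[k], "")[[1]]
    ident <- ident + sum(xa == xb)
    total <- total + 3L
  }
  if (total == 0L) return(0)
  ident / total
}

# column count tables of a profile (matrix rows = seqs, cols = codon columns)
profile_columns <- function(mat) {
  lapply(seq_len(ncol(mat)), function(j) table(mat[, j]))
}

profile_col_score <- function(ta, tb) {
  s <- 0
  na <- sum(ta); nb <- sum(tb)
  for (x in names(ta)) for (y in names(tb)) {
    s <- s + ta[[x]] * tb[[y]] * codon_pair_score_memo(x, y)
  }
  s / (na * nb)
}

# NW on two profiles with linear per-column gap penalty
align_profiles <- function(A, B, gap = -6) {
  ca <- profile_columns(A); cb <- profile_columns(B)
  n <- length(ca); m <- length(cb)
  D <- matrix(0, n + 1L, m + 1L)
  D[, 1L] <- gap * (0:n)
  D[1L, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1L, j + 1L] <- max(D[i, j] + profile_col_score(ca[[i]], cb[[j]]),
                               D[i, j + 1L] + gap,
                               D[i + 1L, j] + gap)
    }
  }
  i <- n; j <- m
  path <- character(0)
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        abs(D[i + 1L, j + 1L] -
            (D[i, j] + profile_col_score(ca[[i]], cb[[j]]))) < 1e-9) {
      path <- c("M", path); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && abs(D[i + 1L, j + 1L] - (D[i, j + 1L] + gap)) < 1e-9) {
      path <- c("A", path); i <- i - 1L
    } else {
      path <- c("B", path); j <- j - 1L
    }
  }
  outA <- matrix(GAP_CODON, nrow(A), length(path),
                 dimnames = list(rownames(A), NULL))
  outB <- matrix(GAP_CODON, nrow(B), length(path),
                 dimnames = list(rownames(B), NULL))
  ia <- 0L; ib <- 0L
  for (k in seq_along(path)) {
    if (path[k] != "B") { ia <- ia + 1L; outA[, k] <- A[, ia] }
    if (path[k] != "A") { ib <- ib + 1L; outB[, k] <- B[, ib] }
  }
  rbind(outA, outB)
}

# fast guide distances from shared 6-mer content
kmer_distance_matrix <- function(seqs, k = 6L) {
  km <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1L), k:n))
  })
  n <- length(seqs)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    inter <- length(intersect(km[[i]], km[[j]]))
    uni <- length(union(km[[i]], km[[j]]))
    d[i, j] <- d[j, i] <- 1 - if (uni) inter / uni else 0
  }
  d
}

#' Progressive multiple alignment of family coding sequences
#'
#' Builds a guide tree by average-linkage clustering of k-mer distances and
#' merges sequences/profiles progressively with codon-aware
#' Needleman-Wunsch, so gap columns always span whole codons.  The result is
#' deterministic and invariant to input order (ties broken on sequence
#' content).
#'
#' @param seqs named character vector of coding sequences.
#' @return Character matrix, rows = input sequences (original names), cols =
#'   codon columns; gap codon `"---"`.
#' @export
align_family <- function(seqs) {
  if (length(seqs) == 0L) stop("no sequences to align")
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%03d", seq_along(seqs))
  if (anyDuplicated(names(seqs))) stop("sequence names must be unique")
  input_names <- names(seqs)
  # canonical processing order: content-sorted for order invariance
  ord <- order(-nchar(seqs), seqs)
  seqs <- seqs[ord]
  if (length(seqs) == 1L) {
    m <- matrix(split_codons(seqs[[1]]), nrow = 1)
    rownames(m) <- names(seqs)
    return(m)
  }
  d <- kmer_distance_matrix(seqs)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  profs <- lapply(seq_along(seqs), function(i) {
    m <- matrix(split_codons(seqs[[i]]), nrow = 1)
    rownames(m) <- names(seqs)[i]
    m
  })
  merged <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    a <- hc$merge[k, 1]; b <- hc$merge[k, 2]
    A <- if (a < 0) profs[[-a]] else merged[[a]]
    B <- if (b < 0) profs[[-b]] else merged[[b]]
    merged[[k]] <- align_profiles(A, B)
  }
  res <- merged[[nrow(hc$merge)]]
  res[input_names, , drop = FALSE]
}
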