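# Ungapped motif discovery in promoter sets: expectation maximisation under
# a ZOOPS (zero-or-one occurrence per sequence) model with a 0-order
# background, a coarse width grid, and iterative masking of discovered
# sites.

seq_to_int <- function(s) {
  x <- match(strsplit(toupper(s), "")[[1]], NUCS)
  x[is.na(x)] <- sample.int(4L, sum(is.na(x)), replace = TRUE)  # rare Ns
  x
}

# log-likelihood-ratio scores of every window of length w (vectorized)
window_scores <- function(x, lt_minus_lbg, w) {
  m <- length(x) - w + 1L
  if (m < 1L) return(numeric(0))
  sc <- numeric(m)
  for (k in seq_len(w)) {
    sc <- sc + lt_minus_lbg[x[seq.int(k, k + m - 1L)], k]
  }
  sc
}

pwm_ic <- function(pwm, bg) {
  sum(vapply(seq_len(ncol(pwm)), function(j) {
    p <- pwm[, j]
    sum(p * log2(pmax(p, 1e-12) / bg))
  }, 0))
}

#' IUPAC consensus string of a position weight matrix
#' @param pwm 4 x w probability matrix (rows A, C, G, T).
#' @return Character consensus using IUPAC ambiguity codes.
#' @export
pwm_consensus <- function(pwm) {
  map <- Biostrings::IUPAC_CODE_MAP
  inv <- stats::setNames(names(map), vapply(map, function(s)
    paste(sort(strsplit(s, "")[[1]]), collapse = ""), ""))
  paste(vapply(seq_len(ncol(pwm)), function(j) {
    inc <- NUCS[pwm[, j] >= 0.25]
    if (!length(inc)) inc <- NUCS
    inv[[paste(sort(inc), collapse = "")]]
  }, ""), collapse = "")
}

# one EM run from a seeded PWM; returns PWM, gamma, log likelihood, and
# per-sequence best site
zoops_em <- function(ints, ok_list, pwm0, bg, max_iter = 200L, tol = 1e-4) {
  w <- ncol(pwm0)
  pwm <- pwm0
  gamma <- 0.5
  lbg <- log(bg)
  ll_old <- -Inf
  n_seq <- length(ints)
  # per-sequence one-hot window/column masks, computed once
  onehot <- lapply(ints, function(x) {
    m <- length(x) - w + 1L
    if (m < 1L) return(NULL)
    W <- matrix(x[outer(seq_len(m), 0:(w - 1L), "+")], m, w)
    lapply(1:4, function(b) (W == b) * 1)
  })
  for (iter in seq_len(max_iter)) {
    ltm <- log(pwm) - matrix(lbg, 4L, w)
    z_list <- vector("list", n_seq)
    ll <- 0
    for (i in seq_len(n_seq)) {
      sc <- window_scores(ints[[i]], ltm, w)
      ok <- ok_list[[i]]
      if (!length(sc) || !any(ok)) { z_list[[i]] <- numeric(0); next }
      lr <- exp(sc - max(sc[ok]))
      lr[!ok] <- 0
      m_i <- sum(ok)
      denom <- (1 - gamma) * exp(-max(sc[ok])) + (gamma / m_i) * sum(lr)
      z <- (gamma / m_i) * lr / denom
      z_list[[i]] <- z
      ll <- ll + log((1 - gamma) + (gamma / m_i) * sum(exp(sc[ok]))) # true scale
    }
    # M-step: weighted base counts per motif column via an index matrix
    counts <- matrix(0.01, 4L, w)  # pseudocount
    zsum <- 0
    for (i in seq_len(n_seq)) {
      z <- z_list[[i]]
      if (!length(z) || sum(z) < 1e-12 || is.null(onehot[[i]])) next
      for (b in 1:4) {
        counts[b, ] <- counts[b, ] + as.numeric(crossprod(onehot[[i]][[b]], z))
      }
      zsum <- zsum + min(1, sum(z))
    }
    pwm <- sweep(counts, 2, colSums(counts), "/")
    gamma <- min(0.999, max(1e-3, zsum / n_seq))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(pwm = pwm, gamma = gamma, ll = ll, z = z_list)
}

#' Discover ungapped motifs in a promoter set
#'
#' Expectation maximisation under a zero-or-one-occurrence-per-sequence
#' (ZOOPS) model: PWMs are seeded from sampled windows, refined by EM with
#' pseudocount 0.01 against the 0-order background estimated from the
#' input, run over the width grid, and the best width is kept by an
#' information-content x site-count criterion.  Sites of each accepted
#' motif are masked before the next motif is sought.  Deterministic for a
#' fixed seed.
#'
#' @param promoters named character vector (orientation-normalized, TSS at
#'   the 3' end; each <= 500 bp).
#' @param n_motifs maximal number of motifs to report.
#' @param wmin,wmax motif width bounds (grid {6,8,10,15,20,25,30} clipped).
#' @param n_starts EM restarts (seed windows) per width.
#' @param seed integer seed.
#' @return List of motifs; each is a list with width, pwm, consensus, ic,
#'   gamma, score, occurrences (data.frame seq, offset, strand, score).
#' @export
discover_motifs <- function(promoters, n_motifs = 2L, wmin = 6L, wmax = 30L,
                            n_starts = 5L, seed = 1L) {
  if (length(promoters) < 2L) stop("need >= 2 promoters")
  if (any(nchar(promoters) > 500L)) stop("promoters longer than 500 bp")
  short <- nchar(promoters) < wmin
  if (any(short)) {
    warning(sum(short), " promoter(s) shorter than wmin skipped")
    promoters <- promoters[!short]
  }
  set.seed(derive_seed(seed, 5L))
  ints <- lapply(promoters, seq_to_int)
  all_nt <- unlist(ints)
  bg <- as.numeric(table(factor(all_nt, levels = 1:4)) + 1) / (length(all_nt) + 4)
  widths <- c(6L, 8L, 10L, 15L, 20L, 25L, 30L)
  widths <- widths[widths >= wmin & widths <= wmax]
  masked <- lapply(ints, function(x) logical(length(x)))
  motifs <- list()
  for (mi in seq_len(n_motifs)) {
    best <- NULL
    for (w in widths) {
      ok_list <- lapply(seq_along(ints), function(i) {
        x <- ints[[i]]
        m <- length(x) - w + 1L
        if (m < 1L) return(logical(0))
        cm <- cumsum(c(0L, as.integer(masked[[i]])))
        (cm[seq_len(m) + w] - cm[seq_len(m)]) == 0L
      })
      avail <- do.call(rbind, lapply(seq_along(ints), function(i) {
        ok <- which(ok_list[[i]])
        if (!length(ok)) return(NULL)
        cbind(i, ok)
      }))
      if (is.null(avail) || nrow(avail) < 2L) next
      # seed candidates: the most enriched exact w-mers (a planted motif is
      # the most frequent word at its width), topped up with random windows
      words <- unlist(lapply(seq_along(ints), function(i) {
        ok <- which(ok_list[[i]])
        if (!length(ok)) return(character(0))
        substring(promoters[[i]], ok, ok + w - 1L)
      }))
      tab <- sort(table(words), decreasing = TRUE)
      seeds <- names(tab)[tab >= 2][seq_len(min(2L, sum(tab >= 2)))]
      n_rand <- max(0L, n_starts - length(seeds))
      if (n_rand > 0L) {
        picks <- avail[sample.int(nrow(avail), n_rand, replace = TRUE), ,
                       drop = FALSE]
        seeds <- c(seeds, vapply(seq_len(nrow(picks)), function(r) {
          i <- picks[r, 1]; j <- picks[r, 2]
          substring(promoters[[i]], j, j + w - 1L)
        }, ""))
      }
      # short EM pass for every start, full refinement of the best one
      motif_score <- function(fit) {
        n_sites <- sum(vapply(fit$z, function(z)
          length(z) > 0 && max(z) > 0.5, TRUE))
        # information content corrected for the small-sample entropy bias
        # (~3/(2 ln2 n) bits per column, doubled as a safety margin), so
        # that uninformative flanking columns penalize wider widths
        bias <- if (n_sites > 0) 3 / (log(2) * n_sites) else 0
        list(n_sites = n_sites,
             score = n_sites * (pwm_ic(fit$pwm, bg) - w * bias))
      }
      best_w <- NULL
      for (sd_word in seeds) {
        x <- match(strsplit(sd_word, "")[[1]], NUCS)
        x[is.na(x)] <- 1L
        pwm0 <- matrix(0.1, 4L, w)
        pwm0[cbind(x, seq_len(w))] <- 0.7
        fit <- zoops_em(ints, ok_list, pwm0, bg, max_iter = 8L)
        ms <- motif_score(fit)
        if (is.null(best_w) || ms$score > best_w$score) {
          best_w <- c(fit, ms)
        }
      }
      if (is.null(best_w)) next
      fit <- zoops_em(ints, ok_list, best_w$pwm, bg, max_iter = 200L)
      ms <- motif_score(fit)
      if (is.null(best) || ms$score > best$score) {
        best <- list(width = w, pwm = fit$pwm, gamma = fit$gamma,
                     ll = fit$ll, z = fit$z, score = ms$score,
                     n_sites = ms$n_sites, ok_list = ok_list)
      }
    }
    if (is.null(best) || best$n_sites < 2L) break
    occ <- list()
    for (i in seq_along(ints)) {
      z <- best$z[[i]]
      if (!length(z) || max(z) <= 0.5) next
      j <- which.max(z)
      occ[[length(occ) + 1L]] <- data.frame(
        seq = names(promoters)[i], offset = j - 1L, strand = "+",
        score = z[j], stringsAsFactors = FALSE)
      masked[[i]][j:(j + best$width - 1L)] <- TRUE
    }
    best$occurrences <- do.call(rbind, occ)
    best$consensus <- pwm_consensus(best$pwm)
    best$ic <- pwm_ic(best$pwm, bg)
    best$bg <- bg
    best$z <- NULL; best$ok_list <- NULL
    rownames(best$pwm) <- NUCS
    class(best) <- "pwm_motif"
    motifs[[length(motifs) + 1L]] <- best
  }
  motifs
}

# exact null distribution of the integer-scaled log-odds score
pwm_score_distribution <- function(pwm, bg, scale = 100L) {
  lo <- log2(sweep(pmax(pwm, 1e-12), 1, bg, "/"))
  s_int <- round(lo * scale)
  off <- apply(s_int, 2, min)
  probs <- list(1)
  dist <- 1
  for (j in seq_len(ncol(pwm))) {
    col <- s_int[, j] - off[j]
    width <- max(col) + 1L
    colp <- numeric(width)
    for (b in 1:4) colp[col[b] + 1L] <- colp[col[b] + 1L] + bg[b]
    dist <- convolve_dist(dist, colp)
  }
  # report the rounded lattice so observed scores match the distribution
  list(probs = dist, min_score = sum(off) / scale, scale = scale,
       lo = s_int / scale)
}

convolve_dist <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(b)) {
    if (b[i] > 0) out[i:(i + length(a) - 1L)] <- out[i:(i + length(a) - 1L)] + a * b[i]
  }
  out
}

# P(score >= s) under the background
pwm_tail_p <- function(dist, s) {
  idx <- round((s - dist$min_score) * dist$scale) + 1L
  if (idx <= 1L) return(1)
  idx <- min(idx, length(dist$probs))
  sum(dist$probs[idx:length(dist$probs)])
}

#' Combined match p-value of a promoter against a motif set
#'
#' For each motif the best log-odds hit in the promoter is converted to a
#' p-value from the exact score distribution of the PWM under the
#' background; the per-motif p-values are combined with the
#' product-of-p-values formula
#' `P = x * sum_{k=0}^{m-1} (-ln x)^k / k!`, `x = prod(p_i)`.
#'
#' @param promoter promoter sequence.
#' @param motifs list of motifs from [discover_motifs()].
#' @return Combined p-value in (0, 1].
#' @export
combined_match_pvalue <- function(promoter, motifs) {
  if (!length(motifs)) stop("need >= 1 motif")
  ps <- c()
  for (mo in motifs) {
    if (mo$width > nchar(promoter)) next  # skip too-wide motifs
    dist <- pwm_score_distribution(mo$pwm, mo$bg)
    x <- seq_to_int(promoter)
    sc <- window_scores(x, dist$lo, mo$width)
    ps <- c(ps, pwm_tail_p(dist, max(sc)))
  }
  if (!length(ps)) stop("no motif fits in the promoter")
  combine_pvalues(ps)
}

combine_pvalues <- function(ps) {
  x <- prod(ps)
  if (x <= 0) return(0)
  if (x >= 1) return(1)
  m <- length(ps)
  lx <- -log(x)
  min(1, x * sum(vapply(0:(m - 1L), function(k) lx^k / factorial(k), 0)))
}

#' Scan sequences for motif occurrences at a relative-score threshold
#'
#' Scores every window on both strands with the PWM log-odds and reports
#' positions whose score, min-max normalized to the attainable score range,
#' reaches the accuracy threshold.
#'
#' @param seqs named character vector (e.g. genome contigs).
#' @param motif a motif from [discover_motifs()].
#' @param accuracy relative-score threshold in (0, 1] (default 0.70).
#' @return data.frame: seq, offset (0-based, forward strand), strand,
#'   score, relscore.
#' @export
pwm_scan <- function(seqs, motif, accuracy = 0.70) {
  stopifnot(accuracy > 0, accuracy <= 1)
  lo <- log2(sweep(pmax(motif$pwm, 1e-12), 1, motif$bg, "/"))
  smax <- sum(apply(lo, 2, max))
  smin <- sum(apply(lo, 2, min))
  out <- list()
  for (nm in names(seqs)) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seqs[[nm]] else revcomp_chr(seqs[[nm]])
      x <- seq_to_int(s)
      sc <- window_scores(x, lo, motif$width)
      rel <- (sc - smin) / (smax - smin)
      hit <- which(rel >= accuracy)
      if (!length(hit)) next
      off <- if (strand == "+") hit - 1L else nchar(s) - (hit - 1L) - motif$width
      out[[length(out) + 1L]] <- data.frame(
        seq = nm, offset = off, strand = strand, score = sc[hit],
        relscore = rel[hit], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(seq = character(0), offset = integer(0),
                      strand = character(0), score = numeric(0),
                      relscore = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Positional conservation of motif occurrences
#'
#' Standard deviation of the occurrence offsets measured from the
#' transcription-start end (3' end) of each promoter; motifs whose SD is at
#' most `sd_bound` are flagged positionally conserved.
#'
#' @param occurrences occurrence data.frame (columns seq, offset).
#' @param promoters the promoter set the occurrences refer to.
#' @param width motif width (to measure motif start relative to the TSS).
#' @param sd_bound conservation bound in bp (default 10).
#' @return List: offsets_from_tss, sd, conserved.
#' @export
positional_conservation <- function(occurrences, promoters, width,
                                    sd_bound = 10) {
  if (nrow(occurrences) < 2L) stop("need >= 2 occurrences")
  lens <- nchar(promoters)[occurrences$seq]
  d <- lens - occurrences$offset
  s <- stats::sd(d)
  list(offsets_from_tss = d, sd = s, conserved = s <= sd_bound)
}
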