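#' Jukes-Cantor distance between two aligned sequences
#'
#' Columns where either sequence has a gap or ambiguity are excluded
#' pairwise.  With mismatch fraction p, d = -(3/4) ln(1 - 4p/3); p >= 0.75
#' is saturated and returns `Inf` with a `saturated` attribute.
#'
#' @param a,b aligned nucleotide strings of equal length.
#' @return Distance in substitutions/site.
#' @export
jc_distance <- function(a, b) {
  xa <- strsplit(toupper(a), "")[[1]]
  xb <- strsplit(toupper(b), "")[[1]]
  if (length(xa) != length(xb)) stop("sequences must be aligned (equal length)")
  ok <- xa %in% NUCS & xb %in% NUCS
  n <- sum(ok)
  if (n == 0L) stop("no comparable columns")
  p <- sum(xa[ok] != xb[ok]) / n
  if (p >= 0.75) {
    return(structure(Inf, saturated = TRUE))
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' Jukes-Cantor distance matrix of an alignment
#'
#' @param seqs named character vector of aligned nucleotide sequences.
#' @return Symmetric numeric matrix (substitutions/site).
#' @export
jc_matrix <- function(seqs) {
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    d[i, j] <- d[j, i] <- as.numeric(jc_distance(seqs[[i]], seqs[[j]]))
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via \pkg{ape}); negative branch-length
#' estimates are clamped to zero and flagged in the `clamped` attribute.
#'
#' @param d symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return An [ape::nj()] `phylo` object (unrooted).
#' @export
nj_tree <- function(d) {
  if (nrow(d) < 3L) stop("neighbor joining needs >= 3 taxa")
  tr <- ape::nj(stats::as.dist(d))
  neg <- tr$edge.length < 0
  tr$edge.length[neg] <- 0
  attr(tr, "clamped") <- sum(neg)
  tr
}

# single-nucleotide neighbours of a codon at one position
codon_neighbors <- function(codon, pos) {
  vapply(setdiff(NUCS, substr(codon, pos, pos)), function(nt) {
    x <- codon
    substr(x, pos, pos) <- nt
    x
  }, "")
}

#' Nei-Gojobori synonymous/nonsynonymous site counts of a codon
#'
#' Per position, the fraction of the three single-nucleotide mutations that
#' are synonymous, with STOP-creating mutations excluded from the
#' denominator.  S is the sum of those fractions over the three positions;
#' N is `3 * (valid mutations / 9) - S`.
#'
#' @param codon sense codon (no gaps or ambiguity).
#' @return Named numeric vector `c(N = , S = )`.
#' @export
ng_site_counts <- function(codon) {
  aa <- codon_table()
  if (!codon %in% names(aa)) stop("not a codon: ", codon)
  if (aa[[codon]] == "*") stop("STOP codon has no site counts")
  S <- 0; valid <- 0L
  for (pos in 1:3) {
    nb <- codon_neighbors(codon, pos)
    sense <- nb[aa[nb] != "*"]
    valid <- valid + length(sense)
    if (length(sense)) {
      S <- S + sum(aa[sense] == aa[[codon]]) / length(sense)
    }
  }
  c(N = 3 * (valid / 9) - S, S = S)
}

#' Nei-Gojobori substitution-path counts between two codons
#'
#' Averages the numbers of nonsynonymous and synonymous steps over all
#' minimal single-nucleotide mutation paths between the codons; paths that
#' pass through a STOP codon are excluded (if all are excluded, all paths
#' are used as a fallback).
#'
#' @param a,b sense codons.
#' @return Named numeric vector `c(n = , s = )`.
#' @export
ng_path_counts <- function(a, b) {
  aa <- codon_table()
  if (aa[[a]] == "*" || aa[[b]] == "*") stop("STOP codons are excluded")
  diffs <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (length(diffs) == 0L) return(c(n = 0, s = 0))
  perms <- all_permutations(diffs)
  paths <- list()
  for (ord in perms) {
    cur <- a
    steps <- character(0)
    stopped <- FALSE
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(b, pos, pos)
      if (aa[[nxt]] == "*") stopped <- TRUE
      steps <- c(steps, paste0(cur, ">", nxt))
      cur <- nxt
    }
    paths[[length(paths) + 1L]] <- list(steps = steps, stopped = stopped)
  }
  usable <- Filter(function(p) !p$stopped, paths)
  if (!length(usable)) usable <- paths
  ns <- vapply(usable, function(p) {
    cnt <- c(0, 0)
    for (st in p$steps) {
      pair <- strsplit(st, ">", fixed = TRUE)[[1]]
      if (aa[[pair[1]]] == aa[[pair[2]]]) cnt[2] <- cnt[2] + 1 else cnt[1] <- cnt[1] + 1
    }
    cnt
  }, c(0, 0))
  c(n = mean(ns[1, ]), s = mean(ns[2, ]))
}

all_permutations <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_permutations(x[-i])) {
      out[[length(out) + 1L]] <- c(x[i], rest)
    }
  }
  out
}

#' Fitch parsimony substitution events on a tree
#'
#' Two-pass Fitch parsimony per nucleotide site on an arbitrary rooting of
#' the tree; ambiguous leaf states are treated as fully unknown.  Uppass
#' ties resolve toward the parent state (deterministic).  Branch events are
#' the codon differences between reconstructed node states, converted to
#' (n, s) with [ng_path_counts()]; branches whose endpoint codons are not
#' both sense codons are skipped.
#'
#' @param tree `phylo` object whose tip labels name rows of `codon_mat`.
#' @param codon_mat character matrix of codons (rows = taxa, cols = codon
#'   columns), e.g. from [align_family()].
#' @return Matrix with columns `n` and `s`, one row per codon column.
#' @export
fitch_events <- function(tree, codon_mat) {
  if (is.null(rownames(codon_mat)) ||
      !all(tree$tip.label %in% rownames(codon_mat))) {
    stop("tree tips and alignment rows do not match")
  }
  codon_mat <- codon_mat[tree$tip.label, , drop = FALSE]
  nt_mat <- do.call(cbind, lapply(seq_len(ncol(codon_mat)), function(j) {
    t(vapply(codon_mat[, j], function(c3) strsplit(c3, "")[[1]], c("", "", "")))
  }))
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  # postorder traversal of the (arbitrarily) rooted tree
  post <- ape::reorder.phylo(tree, "postorder")
  kids <- split(post$edge[, 2], post$edge[, 1])
  root <- setdiff(unique(post$edge[, 1]), post$edge[, 2])
  n_site <- ncol(nt_mat)
  bit <- stats::setNames(c(1L, 2L, 4L, 8L), NUCS)
  FULL <- 15L
  sets <- matrix(0L, n_node, n_site)
  for (i in seq_len(n_tip)) {
    b <- unname(bit[nt_mat[i, ]])
    b[is.na(b)] <- FULL
    sets[i, ] <- b
  }
  node_order <- unique(post$edge[, 1])  # postorder guarantees children first
  for (nd in node_order) {
    ch <- kids[[as.character(nd)]]
    s <- sets[ch[1], ]
    for (c2 in ch[-1]) {
      inter <- bitwAnd(s, sets[c2, ])
      s <- ifelse(inter > 0L, inter, bitwOr(s, sets[c2, ]))
    }
    sets[nd, ] <- s
  }
  # uppass state assignment: lowest set bit, ties toward parent
  states <- matrix(0L, n_node, n_site)
  low_bit <- function(x) bitwAnd(x, -x)
  states[root, ] <- low_bit(sets[root, ])
  for (k in rev(seq_len(nrow(post$edge)))) {   # preorder
    par <- post$edge[k, 1]; ch <- post$edge[k, 2]
    keep <- bitwAnd(sets[ch, ], states[par, ])
    states[ch, ] <- ifelse(keep > 0L, keep, low_bit(sets[ch, ]))
  }
  nt_of <- stats::setNames(NUCS, c("1", "2", "4", "8"))
  n_codon <- ncol(codon_mat)
  ev <- matrix(0, n_codon, 2, dimnames = list(NULL, c("n", "s")))
  aa <- codon_table()
  for (k in seq_len(nrow(post$edge))) {
    par <- post$edge[k, 1]; ch <- post$edge[k, 2]
    diff_sites <- which(states[par, ] != states[ch, ])
    if (!length(diff_sites)) next
    for (cc in unique((diff_sites - 1L) %/% 3L + 1L)) {
      idx <- (3L * (cc - 1L) + 1L):(3L * cc)
      ca <- paste(nt_of[as.character(states[par, idx])], collapse = "")
      cb <- paste(nt_of[as.character(states[ch, idx])], collapse = "")
      if (is.na(aa[ca]) || is.na(aa[cb]) || aa[[ca]] == "*" || aa[[cb]] == "*") next
      ns <- ng_path_counts(ca, cb)
      ev[cc, ] <- ev[cc, ] + ns
    }
  }
  ev
}

#' Counting-based per-site selection test
#'
#' For each codon column, the expected nonsynonymous fraction
#' `q = N / (N + S)` is computed from the Nei-Gojobori site counts of the
#' column's observed (non-gap, sense) codons.  The observed substitution
#' events n (nonsynonymous) and s (synonymous) from [fitch_events()] are
#' tested against q with a two-tailed binomial test
#' (`p = min(1, 2 * min(tails))`); a site is called `positive` when
#' `n / (n+s) > q` with `p < p_threshold`, `negative` when below, otherwise
#' `neutral`.  Columns with no events are neutral with p = 1.
#'
#' @param events matrix from [fitch_events()].
#' @param codon_mat the codon alignment the events were computed on.
#' @param p_threshold significance threshold (default 0.1).
#' @return data.frame: site, n, s, N, S, q, p, call.
#' @export
slac_site_test <- function(events, codon_mat, p_threshold = 0.1) {
  aa <- codon_table()
  n_codon <- ncol(codon_mat)
  if (nrow(events) != n_codon) stop("events and alignment disagree")
  out <- data.frame(site = seq_len(n_codon), n = events[, "n"],
                    s = events[, "s"], N = NA_real_, S = NA_real_,
                    q = NA_real_, p = 1, call = "neutral",
                    stringsAsFactors = FALSE)
  for (j in seq_len(n_codon)) {
    cods <- codon_mat[, j]
    cods <- cods[cods %in% names(aa)]
    cods <- cods[aa[cods] != "*"]
    if (!length(cods)) next
    ns <- vapply(cods, ng_site_counts, c(N = 0, S = 0))
    out$N[j] <- mean(ns["N", ])
    out$S[j] <- mean(ns["S", ])
    q <- out$N[j] / (out$N[j] + out$S[j])
    out$q[j] <- q
    tot <- round(out$n[j] + out$s[j])
    k <- min(round(out$n[j]), tot)
    if (tot == 0) next
    p_low <- stats::pbinom(k, tot, q)
    p_high <- 1 - stats::pbinom(k - 1, tot, q)
    out$p[j] <- min(1, 2 * min(p_low, p_high))
    if (out$p[j] < p_threshold) {
      out$call[j] <- if (k / tot > q) "positive" else "negative"
    }
  }
  out
}

#' Per-site selection analysis of a codon alignment
#'
#' Convenience wrapper: dereplicates identical rows, builds the JC/NJ tree,
#' reconstructs substitution events by Fitch parsimony and runs the
#' counting test per site.
#'
#' @param codon_mat codon alignment matrix (rows = sequences).
#' @param p_threshold significance threshold.
#' @return List: `sites` (the [slac_site_test()] table) and `tree`.
#' @export
site_selection <- function(codon_mat, p_threshold = 0.1) {
  seqs <- apply(codon_mat, 1, paste, collapse = "")
  seqs <- seqs[!duplicated(seqs)]
  if (length(seqs) < 3L) stop("need >= 3 distinct sequences")
  d <- jc_matrix(gsub("-", "N", seqs))
  d[!is.finite(d)] <- 3  # saturated pairs get a large finite distance
  tr <- nj_tree(d)
  ev <- fitch_events(tr, codon_mat[names(seqs), , drop = FALSE])
  list(sites = slac_site_test(ev, codon_mat[names(seqs), , drop = FALSE],
                              p_threshold),
       tree = tr)
}

#' Simulate a star-phylogeny codon alignment under site-wise selection
#'
#' Each of `n_seq` lineages evolves independently from the reference root
#' CDS under the codon substitution process with the given per-site omega
#' values, yielding a gapless codon alignment with known selective regime
#' per site.
#'
#' @param n_seq number of lineages.
#' @param omega_by_site per-codon omega vector (length 42 for the default
#'   reference).
#' @param sub_rate per-position proposal probability per lineage.
#' @param seed integer seed.
#' @return Codon matrix (rows = `seq001`...) suitable for [site_selection()].
#' @export
simulate_selection_alignment <- function(n_seq = 60L,
                                         omega_by_site = default_omega_by_site(),
                                         sub_rate = 0.12, seed = 1L) {
  set.seed(derive_seed(seed, 4L))
  root <- split_codons(back_translate(reference_mature_peptide()))
  if (length(omega_by_site) != length(root)) {
    stop("omega_by_site must match the reference codon count")
  }
  rows <- t(vapply(seq_len(n_seq), function(i) {
    evolve_codons(root, omega_by_site, sub_rate)
  }, root))
  rownames(rows) <- sprintf("seq%03d", seq_len(n_seq))
  rows
}
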