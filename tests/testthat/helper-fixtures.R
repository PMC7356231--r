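# shared fixtures: all built in code, deterministically

# EMBOSS-style pKa set used in hand-derived charge examples
emboss_pka <- c(NH2 = 8.6, COOH = 3.6, C = 8.5, D = 3.9, E = 4.1,
                H = 6.5, K = 10.8, R = 12.5, Y = 10.1)

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# promoters with one exact planted occurrence of `motif` each
planted_promoters <- function(n = 20L, len = 500L, motif = "TACGATCGGA",
                              seed = 1L, jitter_positions = NULL) {
  set.seed(seed)
  w <- nchar(motif)
  out <- vapply(seq_len(n), function(i) {
    s <- strsplit(rand_dna(len), "")[[1]]
    o <- if (is.null(jitter_positions)) sample.int(len - w + 1L, 1L) else
      jitter_positions[i]
    s[o:(o + w - 1L)] <- strsplit(motif, "")[[1]]
    paste(s, collapse = "")
  }, "")
  stats::setNames(out, sprintf("p%02d", seq_len(n)))
}

# small synthetic family shared by several tests
small_family <- function(seed = 7L, n_individuals = 4L, n_genes = 5L, ...) {
  simulate_family(family_params(n_individuals = n_individuals,
                                n_ancestral_genes = n_genes, seed = seed, ...))
}

# mutate a coding sequence at k codon third-positions (keeps it sense)
mutate_nt <- function(cds, positions, to) {
  x <- strsplit(cds, "")[[1]]
  x[positions] <- to
  paste(x, collapse = "")
}
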