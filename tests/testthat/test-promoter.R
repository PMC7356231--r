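test_that("a planted 10-bp consensus is recovered as the top motif", {
  proms <- planted_promoters(20L, 500L, "TACGATCGGA", seed = 5L)
  mots <- discover_motifs(proms, n_motifs = 1L, seed = 5L)
  expect_identical(mots[[1]]$consensus, "TACGATCGGA")
  expect_equal(mots[[1]]$width, 10L)
  expect_gte(mots[[1]]$n_sites, 18L)
})

test_that("re-running with the same seed gives identical PWMs", {
  proms <- planted_promoters(10L, 300L, "GGATCCTTAA", seed = 2L)
  m1 <- discover_motifs(proms, n_motifs = 1L, wmin = 8L, wmax = 15L, seed = 3L)
  m2 <- discover_motifs(proms, n_motifs = 1L, wmin = 8L, wmax = 15L, seed = 3L)
  expect_identical(m1[[1]]$pwm, m2[[1]]$pwm)
})

test_that("PWM columns stay normalized and EM output is a proper motif", {
  proms <- planted_promoters(10L, 300L, "CATTAGCCAA", seed = 4L)
  mo <- discover_motifs(proms, n_motifs = 1L, wmin = 8L, wmax = 15L,
                        seed = 4L)[[1]]
  expect_equal(colSums(mo$pwm), rep(1, mo$width), tolerance = 1e-9)
  expect_gte(mo$ic, 0)
})

test_that("pure background yields only weak motifs that fail the significance gate", {
  set.seed(6)
  proms <- stats::setNames(vapply(1:12, function(i) rand_dna(300), ""),
                           paste0("p", 1:12))
  mots <- discover_motifs(proms, n_motifs = 1L, wmin = 8L, wmax = 15L, seed = 6L)
  if (length(mots)) {
    # information per column well below a planted exact motif (2 bits/col)
    expect_lt(mots[[1]]$ic / mots[[1]]$width, 1.5)
    p <- combined_match_pvalue(proms[[1]], mots)
    expect_gt(p, 1e-15)
  }
  succeed()
})

test_that("combined match p-values follow the product formula", {
  expect_equal(mytifam:::combine_pvalues(0.01), 0.01)
  expect_equal(mytifam:::combine_pvalues(c(1, 1)), 1)
  x <- 1e-6
  expect_equal(mytifam:::combine_pvalues(c(1e-3, 1e-3)),
               x * (1 - log(x)), tolerance = 1e-9)
  # monotone non-decreasing in each component
  base <- c(1e-3, 1e-2)
  p0 <- mytifam:::combine_pvalues(base)
  expect_gte(mytifam:::combine_pvalues(c(2e-3, 1e-2)), p0)
  expect_gte(mytifam:::combine_pvalues(c(1e-3, 2e-2)), p0)
})

test_that("promoters carrying all planted motifs pass the 1e-15 gate", {
  f <- small_family(seed = 3L, n_individuals = 6L, n_genes = 6L,
                    motif_jitter = 0L)
  loci <- mine_genomes(f$genomes, reference_mature_peptide())
  proms <- loci$promoter[!loci$promoter_truncated]
  names(proms) <- paste0("p", seq_along(proms))
  mots <- discover_motifs(proms, n_motifs = 2L, seed = 1L)
  expect_equal(length(mots), 2L)
  ps <- vapply(proms, function(p) combined_match_pvalue(p, mots), 0)
  expect_true(all(ps < 1e-15))
})

test_that("scanning the motif's own consensus gives relative score 1", {
  proms <- planted_promoters(12L, 300L, "TTGACGTCAA", seed = 9L)
  mo <- discover_motifs(proms, n_motifs = 1L, wmin = 8L, wmax = 15L,
                        seed = 9L)[[1]]
  hits <- pwm_scan(stats::setNames(mo$consensus, "c"), mo, accuracy = 0.99)
  fwd <- hits[hits$strand == "+", ]
  expect_equal(nrow(fwd), 1L)
  expect_equal(fwd$relscore, 1, tolerance = 1e-9)
  # a high-accuracy scan of background yields no hits
  set.seed(10)
  bg <- stats::setNames(rand_dna(5000), "bg")
  expect_equal(nrow(pwm_scan(bg, mo, accuracy = 0.95)), 0L)
})

test_that("genome scans co-locate hits with planted promoters only", {
  f <- small_family(seed = 12L, n_individuals = 2L, n_genes = 4L,
                    motif_jitter = 0L)
  loci <- mine_genomes(f$genomes, reference_mature_peptide())
  proms <- loci$promoter[!loci$promoter_truncated]
  names(proms) <- paste0("p", seq_along(proms))
  mots <- discover_motifs(proms, n_motifs = 1L, wmin = 15L, wmax = 25L, seed = 2L)
  g <- as.character(f$genomes[[1]])
  hits <- pwm_scan(g, mots[[1]], accuracy = 0.9)
  tt <- f$truth[f$truth$individual == "ind01", ]
  in_promoter <- vapply(seq_len(nrow(hits)), function(i) {
    any(tt$contig == hits$seq[i] &
          hits$offset[i] >= tt$promoter_start &
          hits$offset[i] + mots[[1]]$width <= tt$promoter_end)
  }, TRUE)
  expect_true(all(in_promoter))
  expect_gte(nrow(hits), sum(tt$contig %in% names(g)))
})

test_that("positional conservation separates fixed from uniform placements", {
  proms <- planted_promoters(15L, 400L, "ACGTACGTAC", seed = 1L,
                             jitter_positions = rep(101L, 15L))
  occ <- data.frame(seq = names(proms), offset = rep(100L, 15L))
  pc <- positional_conservation(occ, proms, width = 10L)
  expect_equal(pc$sd, 0)
  expect_true(pc$conserved)
  # uniform offsets in [0, 470]: sd near 470/sqrt(12)
  set.seed(3)
  off <- sample(0:470, 200, replace = TRUE)
  occ2 <- data.frame(seq = rep(names(proms)[1], 200), offset = off)
  pc2 <- positional_conservation(occ2, proms, width = 10L)
  expect_gt(pc2$sd, 100)
  expect_false(pc2$conserved)
  # planted with +/-3 jitter stays flagged
  set.seed(4)
  jit <- 101L + sample(-3:3, 15L, replace = TRUE)
  proms3 <- planted_promoters(15L, 400L, "ACGTACGTAC", seed = 2L,
                              jitter_positions = jit)
  occ3 <- data.frame(seq = names(proms3), offset = jit - 1L)
  pc3 <- positional_conservation(occ3, proms3, width = 10L)
  expect_lte(pc3$sd, 3)
  expect_true(pc3$conserved)
})
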