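test_that("dereplication merges identical CDSs and keeps carrier unions", {
  cds <- back_translate(reference_mature_peptide())
  cds2 <- mutate_nt(cds, 6L, "A")   # one nt off
  loci <- data.frame(
    individual = c("i1", "i2", "i3", "i1"),
    cds = c(cds, cds, cds, cds2), stringsAsFactors = FALSE)
  v <- dereplicate(loci)
  expect_equal(nrow(v), 2L)
  expect_equal(v$n_carriers[v$cds == cds], 3L)
  expect_identical(v$carriers[v$cds == cds], "i1,i2,i3")
  expect_equal(nrow(dereplicate(loci[0, ])), 0L)
})

test_that("dereplicated variant count equals the truth distinct-sequence count", {
  f <- small_family(seed = 9L)
  loci <- mine_genomes(f$genomes, reference_mature_peptide())
  v <- dereplicate(loci)
  expect_equal(nrow(v), length(unique(f$truth$cds)))
})

test_that("classification follows the STOP-first and cysteine-array rules", {
  ref <- reference_mature_peptide()
  cds <- back_translate(ref)
  expect_identical(classify_variant(cds), "conventional")
  # TAA at codon 12 forces pseudogene regardless of cysteines
  stopped <- paste0(substr(cds, 1, 33), "TAA", substr(cds, 37, nchar(cds)))
  expect_identical(classify_variant(stopped), "pseudogene")
  # losing exactly Cys1 and Cys5 gives pseudomyticin
  cys <- reference_cys_positions()
  aa <- strsplit(ref, "")[[1]]
  aa[cys[c(1, 5)]] <- "S"
  expect_identical(classify_variant(back_translate(paste(aa, collapse = ""))),
                   "pseudomyticin")
  # any other missing pattern is atypical
  aa2 <- strsplit(ref, "")[[1]]
  aa2[cys[2]] <- "S"
  expect_identical(classify_variant(back_translate(paste(aa2, collapse = ""))),
                   "atypical")
  expect_error(classify_variant("ATGTAA"), "60")
})

test_that("classification matches the generator truth exactly", {
  f <- small_family(seed = 7L, n_individuals = 6L)
  loci <- mine_genomes(f$genomes, reference_mature_peptide())
  v <- classify_variants(dereplicate(loci))
  tmap <- c(conventional = "conventional", pseudogene = "pseudogene",
            cysloss = "pseudomyticin")
  truth_class <- tapply(tmap[f$truth$class], f$truth$cds, `[`, 1)
  expect_identical(v$class, as.character(truth_class[v$cds]))
})

test_that("greedy clustering obeys the identity cut-off", {
  cds <- back_translate(reference_mature_peptide())
  v2 <- dereplicate(data.frame(individual = c("i1", "i2"),
                               cds = c(cds, cds), stringsAsFactors = FALSE))
  expect_equal(nrow(cluster_greedy(v2)$clusters), 1L)
  # ~90% identity pair splits at 0.95
  far <- mutate_nt(cds, seq(3, 42, by = 3), "A")
  idy <- pairwise_identity(cds, far)
  expect_lt(idy, 0.95)
  v3 <- dereplicate(data.frame(individual = c("i1", "i2"),
                               cds = c(cds, far), stringsAsFactors = FALSE))
  expect_equal(nrow(cluster_greedy(v3, 0.95)$clusters), 2L)
  expect_equal(nrow(cluster_greedy(v3, idy)$clusters), 1L)
})

test_that("clusters partition the variants and count is monotone in threshold", {
  f <- small_family(seed = 5L, n_individuals = 5L)
  v <- dereplicate(mine_genomes(f$genomes, reference_mature_peptide()))
  prev <- Inf
  for (thr in c(0.99, 0.95, 0.85, 0.70)) {
    cl <- cluster_greedy(v, thr)
    members <- unlist(strsplit(cl$clusters$members, ","))
    expect_setequal(members, v$variant_id)
    expect_equal(anyDuplicated(members), 0L)
    expect_lte(nrow(cl$clusters), prev)
    prev <- nrow(cl$clusters)
  }
})

test_that("greedy clustering matches an independent re-enumeration of the rule", {
  # independent oracle: same published rule, implemented afresh
  oracle <- function(v, thr) {
    v <- v[order(-nchar(v$cds), v$cds), ]
    reps <- list()
    assign <- character(nrow(v))
    for (i in seq_len(nrow(v))) {
      ids <- vapply(reps, function(r) pairwise_identity(v$cds[i], r), 0)
      k <- if (length(ids) && max(ids) >= thr) which.max(ids) else 0L
      if (k > 0L) assign[i] <- names(reps)[k]
      else { reps[[v$variant_id[i]]] <- v$cds[i]; assign[i] <- v$variant_id[i] }
    }
    stats::setNames(assign, v$variant_id)
  }
  f <- small_family(seed = 13L, n_individuals = 3L, n_genes = 3L)
  v <- dereplicate(mine_genomes(f$genomes, reference_mature_peptide()))
  v <- v[seq_len(min(10L, nrow(v))), ]
  got <- cluster_greedy(v, 0.95)
  want <- oracle(v, 0.95)
  # same partition: members grouped under the same representative
  got_rep <- stats::setNames(
    got$clusters$representative[match(got$assignment, got$clusters$cluster_id)],
    names(got$assignment))
  expect_identical(got_rep[names(want)], want)
})

test_that("consensus takes strict plurality, ties become X, singletons are exact", {
  aln <- rbind(a = c("AAA", "AAA"), b = c("AAA", "AAG"),
               c = c("AAG", "AAG"), d = c("TTT", "AAG"))
  # column 1: AAA x2 vs AAG vs TTT -> AAA; column 2: AAG 3x -> AAG
  cs <- cluster_consensus(c("a", "b", "c", "d"), aln)
  expect_identical(cs$cds, "AAAAAG")
  # 2-2 tie -> ambiguous
  cs2 <- cluster_consensus(c("a", "b"), rbind(a = c("AAA"), b = c("AAG")))
  expect_identical(cs2$cds, "NNN")
  expect_identical(cs2$peptide, "X")
  cs3 <- cluster_consensus("a", aln)
  expect_identical(cs3$cds, "AAAAAA")
  # STOP consensus renders '*'
  cs4 <- cluster_consensus(c("a", "b"), rbind(a = "TAA", b = "TAA"))
  expect_identical(cs4$peptide, "*")
  expect_error(cluster_consensus(character(0), aln), "empty")
})

test_that("PAV matrices and statistics behave on degenerate shapes", {
  v <- data.frame(variant_id = c("v1", "v2"),
                  cds = c("AAA", "CCC"),
                  carriers = c("i1,i2,i3", "i2"),
                  n_carriers = c(3L, 1L), stringsAsFactors = FALSE)
  pav <- build_pav(v, c("i1", "i2", "i3"))
  expect_equal(rowMeans(pav$variant)[["v1"]], 1)
  st <- pav_stats(pav$variant)
  expect_equal(st$n_private, 1L)
  expect_equal(st$n_universal, 1L)
  expect_error(build_pav(v, c("i1", "i2")), "unknown")
  # all-true 3x4: mean per individual 3, all universal
  m <- matrix(TRUE, 3, 4, dimnames = list(paste0("v", 1:3), paste0("i", 1:4)))
  expect_equal(pav_stats(m)$mean_per_individual, 3)
  expect_equal(pav_stats(m)$n_universal, 3L)
  # identity 4x4: mean 1, all rows private
  d <- diag(4) > 0
  dimnames(d) <- list(paste0("v", 1:4), paste0("i", 1:4))
  expect_equal(pav_stats(d)$mean_per_individual, 1)
  expect_equal(pav_stats(d)$n_private, 4L)
})

test_that("the PAV matrix equals the truth presence table", {
  f <- small_family(seed = 21L, n_individuals = 6L)
  v <- dereplicate(mine_genomes(f$genomes, reference_mature_peptide()))
  pav <- build_pav(v, names(f$genomes))$variant
  truth_tab <- with(f$truth, table(cds, factor(individual, levels = names(f$genomes))) > 0)
  got <- pav[order(rownames(pav)), , drop = FALSE]
  want <- truth_tab[v$cds[match(rownames(got), v$variant_id)],
                    colnames(got), drop = FALSE]
  expect_identical(unname(got), unname(as.matrix(want)))
})
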