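test_that("perfect coverage equals the all-substrings brute-force oracle", {
  brute <- function(ref, reads) {
    L <- nchar(ref); cov <- integer(L)
    for (rd in as.character(reads)) {
      for (r in unique(c(rd, mytifam:::revcomp_chr(rd)))) {
        n <- nchar(r)
        if (n > L) next
        for (i in 1:(L - n + 1L)) {
          if (substr(ref, i, i + n - 1L) == r) cov[i:(i + n - 1L)] <- cov[i:(i + n - 1L)] + 1L
        }
      }
    }
    cov
  }
  ref <- rand_dna(400, seed = 9)
  rds <- simulate_reads(ref, 40L, coverage = 5, seed = 2L)
  expect_equal(perfect_coverage(ref, rds)$coverage, brute(ref, rds))
  # short repetitive reference exercises multi-match reads
  ref2 <- paste(rep("ACGTAC", 20), collapse = "")
  rds2 <- simulate_reads(ref2, 12L, coverage = 3, seed = 5L)
  expect_equal(perfect_coverage(ref2, rds2)$coverage, brute(ref2, rds2))
})

test_that("tiled reads leave no zero coverage; a substitution leaves exactly one", {
  ref <- rand_dna(400, seed = 9)
  tl <- simulate_reads(ref, 50L, tile = TRUE)
  cp <- perfect_coverage(ref, tl)
  expect_equal(nrow(cp$zero_intervals), 0L)
  expect_true(all(cp$coverage > 0L))
  mut <- ref
  substr(mut, 200, 200) <- if (substr(ref, 200, 200) == "A") "C" else "A"
  cp2 <- perfect_coverage(mut, tl)
  expect_equal(cp2$zero_intervals, data.frame(start = 199L, end = 200L))
})

test_that("an insertion in the reference shows up as a zero-coverage interval", {
  src <- rand_dna(300, seed = 12)
  ref_ins <- paste0(substr(src, 1, 150), "GGGCC", substr(src, 151, 300))
  rds <- simulate_reads(src, 40L, tile = TRUE)
  cp <- perfect_coverage(ref_ins, rds)
  expect_equal(nrow(cp$zero_intervals), 1L)
  # the strict interior of the 0-based insertion interval [150, 155) can
  # never be covered; the edges may be reached by coincidental base matches
  expect_lte(cp$zero_intervals$start[1], 151)
  expect_gte(cp$zero_intervals$end[1], 154)
})

test_that("expression calls use strict >0.95 identity and flag novel candidates", {
  cds <- back_translate(reference_mature_peptide())  # 126 nt
  # identical transcript -> expressed
  ee <- expression_evidence(c(cl1 = cds), list(T1 = c(t1 = cds)))
  expect_true(ee$expressed["cl1", "T1"])
  expect_equal(ee$best_identity["cl1", "T1"], 1)
  # ~0.94 identity -> absent but novel candidate
  flip <- c(A = "C", C = "A", G = "T", T = "G")
  pos <- c(3, 9, 15, 21, 27, 33, 45, 51)
  x <- strsplit(cds, "")[[1]]
  x[pos] <- flip[x[pos]]
  div <- paste(x, collapse = "")
  idy <- sum(strsplit(cds, "")[[1]] == strsplit(div, "")[[1]]) / nchar(cds)
  ee2 <- expression_evidence(c(cl1 = cds), list(T1 = c(t1 = div)))
  expect_false(ee2$expressed["cl1", "T1"])
  expect_equal(nrow(ee2$novel), 1L)
  expect_lt(ee2$novel$best_identity[1], 0.95)
  # empty transcriptome: all absent
  ee3 <- expression_evidence(c(cl1 = cds), list(T1 = character(0)))
  expect_false(any(ee3$expressed))
})

test_that("lowering the identity threshold never removes an expressed call", {
  f <- small_family(seed = 6L, n_individuals = 3L)
  tx <- simulate_transcriptome(f$truth, "ind01", seed = 1L)
  cons <- stats::setNames(unique(f$truth$cds), paste0("cl", seq_along(unique(f$truth$cds))))
  hi <- expression_evidence(cons, list(T1 = tx$transcripts), id_threshold = 0.95)
  lo <- expression_evidence(cons, list(T1 = tx$transcripts), id_threshold = 0.80)
  expect_true(all(lo$expressed[hi$expressed]))
})

test_that("expression calls match the generator truth exactly", {
  f <- small_family(seed = 19L, n_individuals = 4L)
  ind <- "ind02"
  tx <- simulate_transcriptome(f$truth, ind, seed = 3L)
  rows <- f$truth$individual == ind
  cons <- stats::setNames(f$truth$cds[rows], f$truth$copy_id[rows])
  ee <- expression_evidence(cons, stats::setNames(list(tx$transcripts), ind))
  expect_identical(unname(ee$expressed[, ind]), f$truth$expressed[rows])
})

test_that("RNA edits are recovered exactly and absent when edit_rate is 0", {
  f <- small_family(seed = 23L, n_individuals = 2L, expr_prob = 1)
  ind <- "ind01"
  tx <- simulate_transcriptome(f$truth, ind, edit_rate = 0.02, seed = 7L)
  rows <- tx$truth$individual == ind
  g <- stats::setNames(tx$truth$cds[rows], tx$truth$copy_id[rows])
  reads <- lapply(g, function(s) simulate_reads(s, 30L, tile = TRUE))
  ec <- edit_candidates(g, as.character(tx$transcripts), reads)
  planted <- sort(as.integer(unlist(strsplit(tx$truth$edits[rows], ","))))
  got <- sort(ec$candidates$position[ec$candidates$corroborated])
  expect_identical(got, planted)
  # no spurious candidates without editing
  tx0 <- simulate_transcriptome(f$truth, ind, edit_rate = 0, seed = 7L)
  ec0 <- edit_candidates(g, as.character(tx0$transcripts),
                         lapply(g, function(s) simulate_reads(s, 30L, tile = TRUE)))
  expect_equal(nrow(ec0$candidates), 0L)
  expect_identical(ec0$verdict, "no discrepancies")
})

test_that("variants without a transcript are reported not expressed", {
  g <- c(a = "ATGAAA", b = "ATGCCC")
  tx <- c(tx_a = "ATGAAA")
  ec <- edit_candidates(g, tx)
  expect_identical(ec$not_expressed, "b")
  expect_identical(ec$verdict, "no discrepancies")
})
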