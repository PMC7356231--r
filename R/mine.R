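#' @importFrom utils data
NULL

.blosum_env <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.blosum_env$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosum_env$m <- e$BLOSUM62
  }
  .blosum_env$m
}

# translate one reading frame (1..3) of a forward nucleotide string
frame_peptide <- function(dna_chr, frame) {
  n <- nchar(dna_chr)
  usable <- 3L * ((n - frame + 1L) %/% 3L)
  if (usable < 3L) return("")
  starts <- seq.int(frame, frame + usable - 3L, by = 3L)
  aa <- codon_table()[substring(dna_chr, starts, starts + 2L)]
  aa[is.na(aa)] <- "X"  # codons containing N
  paste(aa, collapse = "")
}

#' Six-frame translated local search for family loci
#'
#' Aligns a query peptide against all six reading frames of each contig with
#' Smith-Waterman local alignment (BLOSUM62, gap open 11, extend 1; STOP
#' codons translate to `*`, scored -4 against residues as in the standard
#' matrix).  Hits are mapped back to forward-strand nucleotide coordinates
#' (0-based, half-open).  Within a contig, hits whose intervals overlap are
#' reduced to the highest-scoring one; repeated matches in the same frame
#' are found by iterative masking.
#'
#' @param contigs named [Biostrings::DNAStringSet-class] or named character
#'   vector of contig sequences.
#' @param query_peptide query amino-acid string (>= 10 residues).
#' @param score_min minimal raw alignment score to keep a hit.
#' @param identity_min minimal fraction of identical aligned residues
#'   (replaces manual curation of raw hits).
#' @return data.frame with columns contig, frame (+1..+3 / -1..-3), strand,
#'   start, end, score, pident, qstart, qend, qlen.
#' @export
translated_search <- function(contigs, query_peptide, score_min = 60,
                              identity_min = 0.40) {
  if (is(contigs, "DNAStringSet")) contigs <- as.character(contigs)
  if (length(contigs) == 0L) return(empty_hits())
  if (is.null(names(contigs)) || anyNA(names(contigs))) {
    stop("contigs must be named")
  }
  if (any(grepl("[^ACGTNacgtn]", contigs))) {
    stop("contigs contain non-IUPAC characters")
  }
  query_peptide <- as.character(query_peptide)
  if (nchar(query_peptide) < 10L) stop("query must be >= 10 aa")
  if (score_min <= 0) stop("score_min must be positive")
  qlen <- nchar(query_peptide)
  qaa <- Biostrings::AAString(query_peptide)
  mat <- blosum62()

  # all six frame peptides of all contigs, aligned in one vectorized call
  # per masking round (the query is the alignment subject; local score is
  # symmetric and pattern/subject ranges swap roles)
  frames <- list()
  for (cid in names(contigs)) {
    fwd <- toupper(contigs[[cid]])
    rev <- revcomp_chr(fwd)
    clen <- nchar(fwd)
    for (fr in 1:3) {
      for (strand in c("+", "-")) {
        pep <- frame_peptide(if (strand == "+") fwd else rev, fr)
        if (nchar(pep) < 4L) next
        frames[[length(frames) + 1L]] <- list(contig = cid, fr = fr,
                                              strand = strand, clen = clen,
                                              pep = pep)
      }
    }
  }
  if (!length(frames)) return(empty_hits())
  peps <- vapply(frames, `[[`, "", "pep")
  active <- seq_along(frames)
  hits <- list()
  for (iter in 1:10) {
    if (!length(active)) break
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(peps[active]), qaa, type = "local",
      substitutionMatrix = mat, gapOpening = 11, gapExtension = 1)
    sc <- Biostrings::score(pa)
    keep <- which(sc >= score_min)
    if (!length(keep)) break
    fstart <- Biostrings::start(Biostrings::pattern(pa))[keep]
    fend <- Biostrings::end(Biostrings::pattern(pa))[keep]
    qstart <- Biostrings::start(Biostrings::subject(pa))[keep]
    qend <- Biostrings::end(Biostrings::subject(pa))[keep]
    al_len <- nchar(as.character(Biostrings::pattern(pa)))[keep]
    nmat <- Biostrings::nmatch(pa)[keep]
    for (j in seq_along(keep)) {
      fi <- frames[[active[keep[j]]]]
      nt_a <- (fi$fr - 1L) + 3L * (fstart[j] - 1L)
      nt_b <- (fi$fr - 1L) + 3L * fend[j]
      if (fi$strand == "+") {
        iv <- c(nt_a, nt_b); frame_lab <- fi$fr
      } else {
        iv <- c(fi$clen - nt_b, fi$clen - nt_a); frame_lab <- -fi$fr
      }
      pident <- nmat[j] / al_len[j]
      if (pident >= identity_min) {
        hits[[length(hits) + 1L]] <- data.frame(
          contig = fi$contig, frame = frame_lab, strand = fi$strand,
          start = iv[1], end = iv[2], score = sc[keep[j]], pident = pident,
          qstart = qstart[j], qend = qend[j], qlen = qlen,
          stringsAsFactors = FALSE)
      }
      idx <- active[keep[j]]
      substr(peps[idx], fstart[j], fend[j]) <-
        paste(rep("X", fend[j] - fstart[j] + 1L), collapse = "")
    }
    active <- active[keep]
  }
  if (!length(hits)) return(empty_hits())
  res <- do.call(rbind, hits)
  res <- do.call(rbind, lapply(split(res, res$contig), merge_hits))
  res <- res[order(match(res$contig, names(contigs)), res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_hits <- function() {
  data.frame(contig = character(0), frame = integer(0), strand = character(0),
             start = integer(0), end = integer(0), score = numeric(0),
             pident = numeric(0), qstart = integer(0), qend = integer(0),
             qlen = integer(0), stringsAsFactors = FALSE)
}

# reduce overlapping hits of one contig to the best-scoring representative
merge_hits <- function(h) {
  ir <- IRanges::IRanges(h$start + 1L, h$end)
  grp <- S4Vectors::subjectHits(IRanges::findOverlaps(ir, IRanges::reduce(ir)))
  keep <- unlist(lapply(split(seq_len(nrow(h)), grp), function(idx) {
    idx[which.max(h$score[idx])]
  }))
  h[sort(keep), , drop = FALSE]
}

#' Extract a gene locus (exon-3 CDS and promoter) from a hit
#'
#' The hit interval is extended to the full query span (unaligned query
#' flanks projected codon-wise onto the contig), trimmed to codon
#' boundaries, and sliced on the sense strand.  The promoter is the region
#' immediately upstream of the gene start on the sense strand, up to
#' `promoter_len` bases, truncated (and flagged) at contig edges.
#'
#' @param contig contig sequence (character or DNAString).
#' @param hit one-row data.frame as produced by [translated_search()].
#' @param promoter_len upstream length to extract (default 500).
#' @return List of class `gene_locus`: contig, strand, start, end, cds,
#'   promoter, promoter_truncated, cds_truncated.
#' @export
extract_locus <- function(contig, hit, promoter_len = 500L,
                          query_peptide = NULL) {
  contig <- toupper(as.character(contig))
  clen <- nchar(contig)
  if (hit$start < 0 || hit$end > clen) stop("hit lies outside contig")
  up_aa <- hit$qstart - 1L
  dn_aa <- hit$qlen - hit$qend
  if (hit$strand == "+") {
    a <- hit$start - 3L * up_aa
    b <- hit$end + 3L * dn_aa
  } else {
    a <- hit$start - 3L * dn_aa
    b <- hit$end + 3L * up_aa
  }
  # When the local alignment opened a gap, the extended interval is longer
  # (or shorter) than the query span.  For substitution-only families the
  # true placement is gapless: evaluate every frame-consistent placement of
  # a query-length window between the two end anchors and keep the best.
  want <- 3L * hit$qlen
  if (!is.null(query_peptide) && (b - a) != want) {
    a1 <- a
    a2 <- b - want
    cand <- seq(min(a1, a2), max(a1, a2), by = 3L)
    cand <- cand[cand >= 0L & cand + want <= clen]
    if (length(cand)) {
      qaa <- strsplit(as.character(query_peptide), "")[[1]]
      mat <- blosum62()
      sc <- vapply(cand, function(s) {
        w <- substr(contig, s + 1L, s + want)
        if (hit$strand == "-") w <- revcomp_chr(w)
        pep <- strsplit(translate_cds(w), "")[[1]]
        sum(mat[cbind(pep, qaa)])
      }, 0)
      a <- cand[which.max(sc)]
      b <- a + want
    }
  }
  cds_trunc <- FALSE
  if (a < 0L) { a <- a + 3L * ceiling(-a / 3); cds_trunc <- TRUE }
  if (b > clen) { b <- b - 3L * ceiling((b - clen) / 3); cds_trunc <- TRUE }
  cds <- substr(contig, a + 1L, b)
  if (hit$strand == "-") cds <- revcomp_chr(cds)
  if (hit$strand == "+") {
    pa <- max(0L, a - promoter_len); pb <- a
    prom <- substr(contig, pa + 1L, pb)
  } else {
    pa <- b; pb <- min(clen, b + promoter_len)
    prom <- revcomp_chr(substr(contig, pa + 1L, pb))
  }
  structure(list(contig = hit$contig %||% NA_character_, strand = hit$strand,
                 start = a, end = b, cds = cds, promoter = prom,
                 promoter_truncated = nchar(prom) < promoter_len,
                 cds_truncated = cds_trunc),
            class = "gene_locus")
}

#' Promoter sequence of an extracted locus
#' @param locus a `gene_locus` from [extract_locus()].
#' @return Character string (may be empty for edge-truncated loci).
#' @export
extract_promoter <- function(locus) {
  stopifnot(inherits(locus, "gene_locus"))
  locus$promoter
}

#' Mine a set of individual genomes for family loci
#'
#' Runs [translated_search()] on every individual assembly and extracts the
#' CDS and promoter of each hit.
#'
#' @param genomes named list of [Biostrings::DNAStringSet-class], one per
#'   individual.
#' @param query_peptide mature-peptide query.
#' @param score_min,identity_min passed to [translated_search()].
#' @param promoter_len passed to [extract_locus()].
#' @return data.frame with one row per mined locus: individual, contig,
#'   strand, start, end, score, pident, cds, promoter, promoter_truncated.
#' @export
mine_genomes <- function(genomes, query_peptide, score_min = 60,
                         identity_min = 0.40, promoter_len = 500L) {
  rows <- list()
  for (ind in names(genomes)) {
    contigs <- as.character(genomes[[ind]])
    hits <- translated_search(contigs, query_peptide, score_min, identity_min)
    for (r in seq_len(nrow(hits))) {
      loc <- extract_locus(contigs[[hits$contig[r]]], hits[r, , drop = FALSE],
                           promoter_len, query_peptide)
      rows[[length(rows) + 1L]] <- data.frame(
        individual = ind, contig = hits$contig[r], strand = hits$strand[r],
        start = loc$start, end = loc$end, score = hits$score[r],
        pident = hits$pident[r], cds = loc$cds, promoter = loc$promoter,
        promoter_truncated = loc$promoter_truncated,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(individual = character(0), contig = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), score = numeric(0),
                      pident = numeric(0), cds = character(0),
                      promoter = character(0), promoter_truncated = logical(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
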