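# Expression evidence and RNA-editing assessment: cluster consensus
# sequences vs transcriptome assemblies (local-alignment identity), and
# exact-match read coverage of transcripts.

# best local-alignment identity of a query against a set of contigs;
# identity = identical positions / query length (both strands tried)
best_local_identity <- function(query, contigs) {
  if (!length(contigs)) return(c(identity = 0, which = NA_integer_))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1)
  q <- Biostrings::DNAString(query)
  best <- 0; best_i <- NA_integer_
  subs <- Biostrings::DNAStringSet(contigs)
  for (strand in 1:2) {
    pa <- Biostrings::pairwiseAlignment(
      subs, q, type = "local", substitutionMatrix = mat,
      gapOpening = 10, gapExtension = 4)
    idy <- Biostrings::nmatch(pa) / nchar(query)
    i <- which.max(idy)
    if (idy[i] > best) { best <- idy[i]; best_i <- i }
    subs <- Biostrings::reverseComplement(subs)
  }
  c(identity = best, which = best_i)
}

#' Expression evidence of clusters in transcriptome assemblies
#'
#' Each cluster consensus (mature region) is locally aligned against every
#' contig of each transcriptome; a cluster is called expressed in a
#' transcriptome when its best identity is strictly greater than
#' `id_threshold`.  Contigs that reach at least `family_floor` identity to
#' some cluster but stay below the threshold against all clusters are
#' reported as novel-cluster candidates; contigs at exactly the threshold
#' are neither expressed evidence nor novel (logged).
#'
#' @param consensus named character vector of cluster consensus sequences
#'   (ambiguity characters are tolerated but reduce identity; supply the
#'   mature-region consensus).
#' @param transcriptomes named list of [Biostrings::DNAStringSet-class] (or
#'   named character vectors), one per transcriptome assembly.
#' @param id_threshold expression identity threshold (default 0.95).
#' @param family_floor minimal identity for a contig to count as
#'   family-like at all (novel-candidate floor, default 0.70).
#' @return List: `expressed` (logical matrix clusters x transcriptomes),
#'   `best_identity` (numeric matrix), `novel` (data.frame transcriptome,
#'   contig, best_identity).
#' @export
expression_evidence <- function(consensus, transcriptomes,
                                id_threshold = 0.95, family_floor = 0.70) {
  cl <- names(consensus)
  tx <- names(transcriptomes)
  expressed <- matrix(FALSE, length(cl), length(tx), dimnames = list(cl, tx))
  bestid <- matrix(0, length(cl), length(tx), dimnames = list(cl, tx))
  novel <- list()
  for (t in tx) {
    contigs <- as.character(transcriptomes[[t]])
    if (!length(contigs)) next
    # per-contig best identity over clusters, to find novel candidates
    contig_best <- stats::setNames(numeric(length(contigs)), names(contigs))
    for (cid in cl) {
      ids <- vapply(contigs, function(ct)
        best_local_identity(consensus[[cid]], stats::setNames(ct, "x"))[["identity"]],
        0)
      bestid[cid, t] <- max(ids, 0)
      expressed[cid, t] <- bestid[cid, t] > id_threshold
      contig_best <- pmax(contig_best, ids)
    }
    nv <- which(contig_best >= family_floor & contig_best < id_threshold)
    for (i in nv) {
      novel[[length(novel) + 1L]] <- data.frame(
        transcriptome = t, contig = names(contigs)[i] %||% as.character(i),
        best_identity = contig_best[i], stringsAsFactors = FALSE)
    }
  }
  novel <- if (length(novel)) do.call(rbind, novel) else
    data.frame(transcriptome = character(0), contig = character(0),
               best_identity = numeric(0), stringsAsFactors = FALSE)
  rownames(novel) <- NULL
  list(expressed = expressed, best_identity = bestid, novel = novel)
}

#' Exact-match read coverage of a reference
#'
#' A read contributes coverage only where it matches the reference exactly
#' over its whole length (the equivalent of mapping with length fraction 1
#' and similarity fraction 1); both strands are tried.  Zero-coverage
#' positions are reported as maximal disjoint intervals and flag candidate
#' genome/transcript discrepancies.
#'
#' @param reference reference sequence (character or DNAString).
#' @param reads [Biostrings::DNAStringSet-class] or character vector.
#' @return List of class `coverage_profile`: `coverage` (integer vector),
#'   `zero_intervals` (data.frame start, end; 0-based half-open).
#' @export
perfect_coverage <- function(reference, reads) {
  reference <- as.character(reference)
  L <- nchar(reference)
  cov <- integer(L)
  ref <- Biostrings::DNAString(reference)
  reads <- as.character(reads)
  # count multiplicity of identical reads once
  tab <- table(reads)
  for (rd in names(tab)) {
    mult <- as.integer(tab[[rd]])
    for (r in c(rd, revcomp_chr(rd))) {
      m <- Biostrings::matchPattern(r, ref)
      st <- Biostrings::start(m); en <- Biostrings::end(m)
      for (k in seq_along(st)) {
        cov[st[k]:en[k]] <- cov[st[k]:en[k]] + mult
      }
      if (rd == revcomp_chr(rd)) break  # palindromic read: count once
    }
  }
  r <- rle(cov == 0L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  zi <- data.frame(start = starts[r$values] - 1L, end = ends[r$values])
  structure(list(coverage = cov, zero_intervals = zi),
            class = "coverage_profile")
}

#' RNA-editing candidates from genome/transcript comparison
#'
#' For each genomic variant with a paired transcript: (a) the two sequences
#' are compared position by position (aligned, equal length expected for
#' substitution-only editing) to list mismatches; (b) genome-derived reads
#' are mapped to the transcript with [perfect_coverage()] and a mismatch is
#' corroborated when it falls in a zero-coverage interval.  With no
#' corroborated candidates the verdict is `"no discrepancies"` (fully
#' genomic origin of the variation).
#'
#' @param genomic named character vector of genomic CDSs.
#' @param transcripts named character vector; names must pair with
#'   `genomic` (`tx_<name>`); variants without a transcript are reported
#'   not expressed and excluded from editing statistics.
#' @param reads named list: for each paired name, the genome-derived read
#'   set to corroborate with (optional; without reads, corroboration is
#'   skipped and direct mismatches are reported).
#' @return List: `candidates` (data.frame variant, position (0-based),
#'   genomic, transcript, corroborated), `not_expressed` (character),
#'   `verdict`.
#' @export
edit_candidates <- function(genomic, transcripts, reads = list()) {
  if (is.null(names(genomic))) stop("genomic variants must be named")
  out <- list()
  not_expr <- character(0)
  for (nm in names(genomic)) {
    tnm <- paste0("tx_", nm)
    if (!tnm %in% names(transcripts)) {
      not_expr <- c(not_expr, nm)
      next
    }
    g <- toupper(genomic[[nm]]); tr <- toupper(transcripts[[tnm]])
    if (nchar(g) != nchar(tr)) stop("paired sequences differ in length: ", nm)
    ga <- strsplit(g, "")[[1]]; ta <- strsplit(tr, "")[[1]]
    mm <- which(ga != ta)
    if (!length(mm)) next
    corr <- rep(NA, length(mm))
    if (tnm %in% names(reads) || nm %in% names(reads)) {
      rd <- reads[[if (tnm %in% names(reads)) tnm else nm]]
      cp <- perfect_coverage(tr, rd)
      corr <- cp$coverage[mm] == 0L
    }
    out[[length(out) + 1L]] <- data.frame(
      variant = nm, position = mm - 1L, genomic = ga[mm], transcript = ta[mm],
      corroborated = corr, stringsAsFactors = FALSE)
  }
  cand <- if (length(out)) do.call(rbind, out) else
    data.frame(variant = character(0), position = integer(0),
               genomic = character(0), transcript = character(0),
               corroborated = logical(0), stringsAsFactors = FALSE)
  n_confirmed <- sum(is.na(cand$corroborated) | cand$corroborated)
  list(candidates = cand, not_expressed = not_expr,
       n_candidates = n_confirmed,
       verdict = if (n_confirmed == 0L) "no discrepancies"
                 else "editing candidates found")
}
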