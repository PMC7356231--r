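#' Reference mature peptide used as family ancestor and mining query
#'
#' A synthetic 42-residue mature peptide emulating the composition of a
#' cysteine-rich, CS-alpha-beta type antimicrobial peptide: eight conserved
#' cysteines (engaged in four disulfide bridges in the real molecules), a
#' C-terminal arginine marking the propeptide cleavage boundary, and a
#' slightly cationic residue balance (4 K, 3 R, 2 H vs 1 D, 1 E) that places
#' the isoelectric point between 7 and 8 and the net charge at pH 7.4 in the
#' low positive range, as observed for myticin mature peptides.
#'
#' @return Single character string of 42 amino acids.
#' @export
reference_mature_peptide <- function() {
  "QSCASRCTKHGFCPGGKLFGSCTDGAKCCVSKHERSLCGCVR"
}

#' Positions of the eight conserved cysteines on the reference mature peptide
#'
#' @return Integer vector of length 8 (1-based residue positions, ascending).
#' @export
reference_cys_positions <- function() {
  c(3L, 7L, 13L, 22L, 28L, 29L, 38L, 40L)
}

#' Default per-codon nonsynonymous scaling factors
#'
#' Omega (dN/dS scaling) for each of the 42 mature-peptide codons: 0 at the
#' eight frozen cysteine codons, 0.05 at four structurally constrained sites
#' (including the C-terminal arginine), 5 at ten hypervariable sites, and 1
#' (neutral) elsewhere.
#'
#' @return Numeric vector of length 42.
#' @export
default_omega_by_site <- function() {
  omega <- rep(1, 42)
  omega[reference_cys_positions()] <- 0
  omega[c(19L, 21L, 25L, 42L)] <- 0.05
  omega[c(2L, 5L, 8L, 12L, 18L, 23L, 26L, 30L, 36L, 41L)] <- 5
  omega
}

#' Default planted promoter motifs
#'
#' Two ordered motifs planted upstream of every gene copy: a 20-bp distal
#' element and a 10-bp TATA-like proximal element, mirroring the serial,
#' positionally conserved motif architecture seen in myticin promoters.
#'
#' @return Named character vector of motif consensus sequences (A/C/G/T).
#' @export
default_promoter_motifs <- function() {
  c(distal = "CAATCGGTTACCGATAAGCT", tata = "CTATAAAAGC")
}

# preferred codon per amino acid, for deterministic back-translation
BACK_TABLE <- c(
  A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT", Q = "CAA",
  E = "GAA", G = "GGT", H = "CAT", I = "ATT", L = "CTG", K = "AAA",
  M = "ATG", F = "TTT", P = "CCT", S = "TCT", T = "ACT", W = "TGG",
  Y = "TAT", V = "GTT"
)

#' Back-translate a peptide with a fixed preferred-codon table
#' @param peptide character scalar of standard amino acids.
#' @return Nucleotide string of length `3 * nchar(peptide)`.
#' @export
back_translate <- function(peptide) {
  aa <- strsplit(peptide, "")[[1]]
  bad <- setdiff(aa, names(BACK_TABLE))
  if (length(bad)) stop("cannot back-translate residues: ", paste(bad, collapse = ","))
  paste(BACK_TABLE[aa], collapse = "")
}

#' Parameters of the synthetic gene family
#'
#' Bundles and validates every knob of the generator.  The defaults are the
#' study conditions the pipeline is validated under: 16 individuals, 10
#' ancestral genes with per-gene presence probability 0.6 (presence/absence
#' variation), private individual-specific duplicates, ~15% divergence
#' between ancestral genes and ~1% within-gene variation, pseudogenes
#' (in-frame STOP) and Cys1/Cys5-loss variants at low rates, 500-bp
#' promoters with two planted ordered motifs, and optional RNA editing.
#'
#' @param n_individuals number of individual genomes.
#' @param n_ancestral_genes number of ancestral family members.
#' @param presence_prob per-gene, per-individual presence probability.
#' @param private_gene_rate Poisson rate of individual-private extra copies.
#' @param sub_rate per-site substitution proposal probability per lineage
#'   (within-gene variation).
#' @param anc_div per-site proposal probability on each ancestral branch
#'   (divergence between ancestral genes).
#' @param private_div extra divergence applied to private copies.
#' @param omega_by_site per-codon nonsynonymous scaling; length must equal
#'   the mature-peptide codon count (42 for the default reference).
#' @param pseudogene_prob probability a copy carries an in-frame STOP.
#' @param cysloss_prob probability a copy loses Cys1 and Cys5.
#' @param expr_prob probability a planted copy is expressed.
#' @param promoter_motifs named character vector of planted motif consensus
#'   sequences (widths 6-30), ordered distal to proximal.
#' @param motif_offsets distance (bp) from each motif start to the
#'   transcription start (promoter 3' end); same length as `promoter_motifs`.
#' @param motif_jitter maximal uniform jitter (bp) applied to each offset.
#' @param promoter_len promoter length in bp.
#' @param contig_len background contig length in bp.
#' @param n_decoys pure-background decoy contigs per individual.
#' @param tandem_fraction fraction of copies appended in tandem to the
#'   previous copy's contig instead of founding their own contig.
#' @param charge_conserve if `TRUE` (default), nonsynonymous substitutions
#'   preserve the residue charge class, keeping the family's pI and net
#'   charge profile narrow as observed for real myticins.
#' @param edit_rate per-base transcript substitution-edit probability.
#' @param seed integer seed; fully determines all output.
#' @return A validated list of class `family_params`.
#' @export
family_params <- function(n_individuals = 16L,
                          n_ancestral_genes = 10L,
                          presence_prob = 0.6,
                          private_gene_rate = 0.5,
                          sub_rate = 0.01,
                          anc_div = 0.15,
                          private_div = 0.01,
                          omega_by_site = default_omega_by_site(),
                          pseudogene_prob = 0.08,
                          cysloss_prob = 0.12,
                          expr_prob = 0.7,
                          promoter_motifs = default_promoter_motifs(),
                          motif_offsets = c(130L, 40L),
                          motif_jitter = 3L,
                          promoter_len = 500L,
                          contig_len = 3000L,
                          n_decoys = 2L,
                          tandem_fraction = 0,
                          charge_conserve = TRUE,
                          edit_rate = 0,
                          seed = 1L) {
  p <- as.list(environment())
  probs <- c(presence_prob, pseudogene_prob, cysloss_prob, expr_prob,
             edit_rate, tandem_fraction, sub_rate, anc_div, private_div)
  if (any(probs < 0 | probs > 1)) stop("probabilities/rates must lie in [0,1]")
  ref <- reference_mature_peptide()
  if (length(omega_by_site) != nchar(ref)) {
    stop("omega_by_site must have one value per mature-peptide codon (",
         nchar(ref), ")")
  }
  if (any(omega_by_site < 0)) stop("omega_by_site must be non-negative")
  w <- nchar(promoter_motifs)
  if (length(promoter_motifs) && (any(w < 6L) || any(w > 30L))) {
    stop("promoter motif widths must lie in [6, 30]")
  }
  if (length(motif_offsets) != length(promoter_motifs)) {
    stop("motif_offsets must match promoter_motifs in length")
  }
  gene_len <- 3L * nchar(ref)
  if (contig_len < promoter_len + gene_len + 20L) {
    stop("contig_len too small to host promoter + gene")
  }
  p$seed <- as.integer(seed)
  class(p) <- "family_params"
  p
}

# residue charge classes used by the charge-conservative evolution mode
charge_class <- function(aa) {
  ifelse(aa %in% c("K", "R", "H"), "basic",
         ifelse(aa %in% c("D", "E"), "acidic",
                ifelse(aa == "C", "thiol", "neutral")))
}

# One pass of the codon substitution process.  Per position a mutation is
# proposed with probability `rate`; STOP-creating proposals are rejected,
# synonymous proposals accepted, nonsynonymous accepted with probability
# min(1, omega).  For omega > 1 an extra nonsynonymous-only proposal round
# at rate `rate * (omega - 1)` raises the realized dN/dS to omega.
# Codons with omega == 0 are fully frozen.  With `charge_conserve`,
# nonsynonymous changes must keep the residue's charge class (basic /
# acidic / thiol / neutral), emulating the charge-neutral diversification
# that keeps the family's pI and net charge in a narrow band.
evolve_codons <- function(codons, omega, rate, charge_conserve = FALSE) {
  aa <- codon_table()
  ok_nonsyn <- function(old, new) {
    if (aa[[new]] == "*" || aa[[new]] == aa[[old]]) return(FALSE)
    !charge_conserve || charge_class(aa[[new]]) == charge_class(aa[[old]])
  }
  for (i in seq_along(codons)) {
    om <- omega[i]
    if (om == 0) next
    cod <- codons[i]
    for (pos in 1:3) {
      if (stats::runif(1) < rate) {
        cand <- cod
        substr(cand, pos, pos) <- sample(setdiff(NUCS, substr(cod, pos, pos)), 1L)
        if (aa[[cand]] == aa[[cod]]) {
          cod <- cand
        } else if (ok_nonsyn(cod, cand) && stats::runif(1) < min(1, om)) {
          cod <- cand
        }
      }
      if (om > 1 && stats::runif(1) < min(1, rate * (om - 1))) {
        cand <- cod
        substr(cand, pos, pos) <- sample(setdiff(NUCS, substr(cod, pos, pos)), 1L)
        if (ok_nonsyn(cod, cand)) cod <- cand
      }
    }
    codons[i] <- cod
  }
  codons
}

plant_promoter <- function(params) {
  prom <- strsplit(random_dna(params$promoter_len), "")[[1]]
  hits <- list()
  for (k in seq_along(params$promoter_motifs)) {
    mot <- unname(params$promoter_motifs[k])
    w <- nchar(mot)
    jit <- if (params$motif_jitter > 0) {
      sample(seq(-params$motif_jitter, params$motif_jitter), 1L)
    } else 0L
    start1 <- params$promoter_len - params$motif_offsets[k] + 1L + jit
    start1 <- max(1L, min(start1, params$promoter_len - w + 1L))
    prom[start1:(start1 + w - 1L)] <- strsplit(mot, "")[[1]]
    hits[[k]] <- c(start = start1 - 1L, end = start1 - 1L + w)  # 0-based half-open
  }
  list(seq = paste(prom, collapse = ""), motifs = hits)
}

#' Simulate a multi-copy AMP gene family across individual genomes
#'
#' Plants mutated copies of a common ancestral gene family into random
#' background contigs, one individual at a time, together with 500-bp
#' promoters carrying ordered sequence motifs immediately upstream of each
#' gene.  Copies are assigned to classes (conventional, pseudogene with an
#' in-frame STOP, or Cys1/Cys5-loss) with the configured probabilities, and
#' every planted feature is recorded in a ground-truth table.
#'
#' Coordinates are 0-based, half-open, on the forward strand of each contig;
#' copies planted on the minus strand keep forward-strand intervals.
#'
#' @param params a [family_params()] object.
#' @return List with elements `genomes` (named list of
#'   [Biostrings::DNAStringSet-class], one per individual), `truth`
#'   (data.frame, one row per planted copy), `ancestors` (character vector of
#'   ancestral CDSs) and `params`.
#' @export
simulate_family <- function(params) {
  stopifnot(inherits(params, "family_params"))
  set.seed(derive_seed(params$seed, 1L))
  ref <- reference_mature_peptide()
  root <- split_codons(back_translate(ref))
  n_cod <- length(root)
  gene_len <- 3L * n_cod
  cys_pos <- reference_cys_positions()

  anc <- lapply(seq_len(params$n_ancestral_genes), function(g) {
    evolve_codons(root, params$omega_by_site, params$anc_div,
                  params$charge_conserve)
  })

  inds <- sprintf("ind%02d", seq_len(params$n_individuals))
  truth <- list()
  genomes <- list()
  copy_n <- 0L

  for (i in seq_along(inds)) {
    ind <- inds[i]
    contigs <- character(0)
    # which ancestral genes are present, plus private duplicates
    present <- which(stats::runif(params$n_ancestral_genes) < params$presence_prob)
    src <- as.list(present)
    n_priv <- stats::rpois(1L, params$private_gene_rate)
    is_priv <- c(rep(FALSE, length(present)), rep(TRUE, n_priv))
    if (n_priv > 0L && params$n_ancestral_genes > 0L) {
      src <- c(src, sample(seq_len(params$n_ancestral_genes), n_priv, replace = TRUE))
    } else {
      is_priv <- is_priv[seq_along(src)]
    }
    last_contig <- NULL
    for (k in seq_along(src)) {
      g <- src[[k]]
      codons <- evolve_codons(anc[[g]], params$omega_by_site, params$sub_rate,
                              params$charge_conserve)
      if (is_priv[k]) {
        codons <- evolve_codons(codons, params$omega_by_site,
                                params$private_div, params$charge_conserve)
      }
      u <- stats::runif(1)
      klass <- if (u < params$pseudogene_prob) {
        "pseudogene"
      } else if (u < params$pseudogene_prob + params$cysloss_prob) {
        "cysloss"
      } else "conventional"
      if (klass == "pseudogene") {
        cand <- setdiff(seq_len(n_cod - 1L), cys_pos)
        pos <- sample(cand, 1L)
        codons[pos] <- sample(c("TAA", "TAG", "TGA"), 1L)
      } else if (klass == "cysloss") {
        codons[cys_pos[c(1L, 5L)]] <- "TCT"  # Cys1 and Cys5 -> Ser
      }
      cds <- paste(codons, collapse = "")
      prom <- plant_promoter(params)
      cassette <- paste0(prom$seq, cds)
      strand <- if (stats::runif(1) < 0.5) "+" else "-"
      tandem <- !is.null(last_contig) && stats::runif(1) < params$tandem_fraction

      if (tandem) {
        cid <- last_contig
        spacer <- random_dna(200L)
        base <- nchar(contigs[[cid]])
        ins <- if (strand == "+") cassette else revcomp_chr(cassette)
        contigs[[cid]] <- paste0(contigs[[cid]], spacer, ins)
        off <- base + 200L
      } else {
        cid <- sprintf("%s_c%03d", ind, length(contigs) + 1L)
        pad_total <- params$contig_len - nchar(cassette)
        left <- sample.int(pad_total - 1L, 1L)
        ins <- if (strand == "+") cassette else revcomp_chr(cassette)
        contigs[[cid]] <- paste0(random_dna(left), ins, random_dna(pad_total - left))
        off <- left
      }
      plen <- params$promoter_len
      if (strand == "+") {
        gstart <- off + plen
        gend <- gstart + gene_len
        pstart <- off
        pend <- off + plen
      } else {
        gstart <- off
        gend <- off + gene_len
        pstart <- off + gene_len
        pend <- pstart + plen
      }
      copy_n <- copy_n + 1L
      motif_str <- paste(
        sprintf("%s:%d-%d", names(params$promoter_motifs),
                vapply(prom$motifs, `[[`, 0L, "start"),
                vapply(prom$motifs, `[[`, 0L, "end")),
        collapse = ";")
      truth[[copy_n]] <- data.frame(
        copy_id = sprintf("copy%04d", copy_n),
        individual = ind, contig = cid, strand = strand,
        start = gstart, end = gend,
        promoter_start = pstart, promoter_end = pend,
        class = klass, gene = if (length(src)) g else NA_integer_,
        private = is_priv[k],
        cds = cds, promoter = prom$seq,
        motifs = if (nzchar(motif_str)) motif_str else "",
        expressed = stats::runif(1) < params$expr_prob,
        edits = "",
        stringsAsFactors = FALSE)
      last_contig <- cid
    }
    for (d in seq_len(params$n_decoys)) {
      contigs[[sprintf("%s_decoy%02d", ind, d)]] <- random_dna(params$contig_len)
    }
    genomes[[ind]] <- Biostrings::DNAStringSet(unlist(contigs))
  }

  truth <- if (length(truth)) do.call(rbind, truth) else empty_truth()
  list(genomes = genomes, truth = truth,
       ancestors = vapply(anc, paste, "", collapse = ""), params = params)
}

empty_truth <- function() {
  data.frame(copy_id = character(0), individual = character(0),
             contig = character(0), strand = character(0),
             start = integer(0), end = integer(0),
             promoter_start = integer(0), promoter_end = integer(0),
             class = character(0), gene = integer(0), private = logical(0),
             cds = character(0), promoter = character(0),
             motifs = character(0), expressed = logical(0),
             edits = character(0), stringsAsFactors = FALSE)
}

#' Simulate the transcriptome of one synthetic individual
#'
#' Emits one transcript contig per expressed planted copy (the exon-3 CDS on
#' the sense strand), optionally applying random substitution edits, which
#' are recorded back into the truth table.
#'
#' @param truth truth table from [simulate_family()].
#' @param individual individual id (e.g. `"ind01"`).
#' @param edit_rate per-base substitution-edit probability.
#' @param seed integer seed.
#' @param expressed optional named logical vector (names = copy ids of this
#'   individual) overriding the truth table's expressed flags.
#' @return List with `transcripts` (DNAStringSet, names = `tx_<copy_id>`) and
#'   the updated `truth` table.
#' @export
simulate_transcriptome <- function(truth, individual, edit_rate = 0,
                                   seed = 1L, expressed = NULL) {
  rows <- which(truth$individual == individual)
  flags <- stats::setNames(truth$expressed[rows], truth$copy_id[rows])
  if (!is.null(expressed)) {
    unknown <- setdiff(names(expressed), names(flags))
    if (length(unknown)) {
      stop("expressed flags reference unknown copies: ",
           paste(unknown, collapse = ","))
    }
    flags[names(expressed)] <- expressed
    truth$expressed[rows] <- unname(flags[truth$copy_id[rows]])
  }
  set.seed(derive_seed(seed, 2L))
  seqs <- character(0)
  for (r in rows) {
    if (!flags[[truth$copy_id[r]]]) next
    tx <- strsplit(truth$cds[r], "")[[1]]
    hit <- which(stats::runif(length(tx)) < edit_rate)
    for (p in hit) tx[p] <- sample(setdiff(NUCS, tx[p]), 1L)
    truth$edits[r] <- paste(hit - 1L, collapse = ",")  # 0-based
    seqs[[paste0("tx_", truth$copy_id[r])]] <- paste(tx, collapse = "")
  }
  list(transcripts = Biostrings::DNAStringSet(seqs), truth = truth)
}

#' Simulate error-free reads from a sequence
#'
#' Reads are exact substrings of the template (or its reverse complement);
#' there is no sequencing-error or quality model.
#'
#' @param sequence character or DNAString template.
#' @param read_length read length in bp.
#' @param coverage target mean per-base depth (ignored when `tile = TRUE`).
#' @param seed integer seed.
#' @param tile if `TRUE`, emit exactly one forward read per start position.
#' @return [Biostrings::DNAStringSet-class] of reads.
#' @export
simulate_reads <- function(sequence, read_length, coverage = 30, seed = 1L,
                           tile = FALSE) {
  sequence <- as.character(sequence)
  len <- nchar(sequence)
  if (read_length > len) stop("read_length exceeds sequence length")
  n_start <- len - read_length + 1L
  if (tile) {
    starts <- seq_len(n_start)
    strands <- rep("+", n_start)
  } else {
    if (coverage <= 0) stop("coverage must be positive")
    set.seed(derive_seed(seed, 3L))
    n_reads <- ceiling(coverage * len / read_length)
    starts <- sample.int(n_start, n_reads, replace = TRUE)
    strands <- sample(c("+", "-"), n_reads, replace = TRUE)
  }
  reads <- substring(sequence, starts, starts + read_length - 1L)
  flip <- strands == "-"
  reads[flip] <- vapply(reads[flip], revcomp_chr, "")
  out <- Biostrings::DNAStringSet(reads)
  names(out) <- sprintf("read%05d_%s_%d", seq_along(reads), strands, starts - 1L)
  out
}

#' Write generator outputs to disk
#'
#' Per-individual genome FASTA, truth table TSV, exon-3 BED (0-based
#' half-open with strand) and a flat key=value echo of the parameters.
#'
#' @param fam result of [simulate_family()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_family <- function(fam, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ind in names(fam$genomes)) {
    Biostrings::writeXStringSet(fam$genomes[[ind]],
                                file.path(dir, paste0(ind, ".fasta")))
  }
  write_tsv(fam$truth, file.path(dir, "truth.tsv"))
  bed <- fam$truth[, c("contig", "start", "end", "copy_id")]
  bed$score <- 0L
  bed$strand <- fam$truth$strand
  utils::write.table(bed, file.path(dir, "truth_exon3.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  p <- fam$params
  keys <- vapply(p, function(v) paste(v, collapse = ","), "")
  writeLines(paste0(names(p), "=", keys), file.path(dir, "params.cfg"))
  invisible(dir)
}
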