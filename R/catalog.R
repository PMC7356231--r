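#' Dereplicate mined loci into unique sequence variants
#'
#' Exact-nucleotide-identical CDSs are merged into a single variant carrying
#' the union of the individuals they were mined from.  Variant ids are
#' assigned deterministically by (length descending, then lexicographic).
#'
#' @param loci data.frame with at least `individual` and `cds` columns (as
#'   from [mine_genomes()]).
#' @return data.frame: variant_id, cds, peptide, carriers
#'   (comma-separated individual ids), n_carriers.
#' @export
dereplicate <- function(loci) {
  if (nrow(loci) == 0L) {
    return(data.frame(variant_id = character(0), cds = character(0),
                      peptide = character(0), carriers = character(0),
                      n_carriers = integer(0), stringsAsFactors = FALSE))
  }
  sp <- split(loci$individual, loci$cds)
  cds <- names(sp)
  ord <- order(-nchar(cds), cds)
  cds <- cds[ord]
  carriers <- vapply(sp[ord], function(x) paste(sort(unique(x)), collapse = ","), "")
  data.frame(
    variant_id = sprintf("var%03d", seq_along(cds)),
    cds = cds,
    peptide = vapply(cds, translate_cds, "", USE.NAMES = FALSE),
    carriers = unname(carriers),
    n_carriers = vapply(strsplit(unname(carriers), ","), length, 0L),
    stringsAsFactors = FALSE)
}

# columns of the reference aligned to each reference position, and the
# pattern residue occupying them
aligned_to_reference <- function(peptide, reference) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(peptide), Biostrings::AAString(reference),
    type = "global", substitutionMatrix = blosum62(),
    gapOpening = 10, gapExtension = 0.5)
  pat <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  res <- rep(NA_character_, nchar(reference))
  rp <- 0L
  for (k in seq_along(sub)) {
    if (sub[k] != "-") {
      rp <- rp + 1L
      res[rp] <- pat[k]
    }
  }
  res
}

#' Classify a variant by ORF integrity and cysteine-array occupancy
#'
#' The STOP test runs first: any in-frame STOP before the final codon makes
#' the variant a pseudogene regardless of its cysteines.  Otherwise the
#' translated peptide is globally aligned to the reference mature peptide
#' and the eight reference cysteine positions are inspected: all eight
#' occupied by Cys gives `conventional`; exactly Cys1 and Cys5 missing gives
#' `pseudomyticin`; any other pattern is `atypical`.
#'
#' @param cds variant CDS (nucleotide string, length multiple of 3, >= 60).
#' @param reference reference mature peptide (default the built-in one).
#' @param cys_positions reference cysteine positions (default built-in).
#' @return One of `"conventional"`, `"pseudogene"`, `"pseudomyticin"`,
#'   `"atypical"`.
#' @export
classify_variant <- function(cds, reference = reference_mature_peptide(),
                             cys_positions = reference_cys_positions()) {
  if (nchar(cds) < 60L) stop("CDS shorter than 60 nt cannot be classified")
  pep <- translate_cds(cds)
  aa <- strsplit(pep, "")[[1]]
  if (any(aa[-length(aa)] == "*")) return("pseudogene")
  occ <- aligned_to_reference(gsub("\\*", "X", pep), reference)
  has_cys <- !is.na(occ[cys_positions]) & occ[cys_positions] == "C"
  if (all(has_cys)) return("conventional")
  missing <- which(!has_cys)
  if (identical(missing, c(1L, 5L))) return("pseudomyticin")
  "atypical"
}

#' Classify all variants of a dereplicated table
#' @param variants data.frame from [dereplicate()].
#' @inheritParams classify_variant
#' @return The input with a `class` column added.
#' @export
classify_variants <- function(variants, reference = reference_mature_peptide(),
                              cys_positions = reference_cys_positions()) {
  variants$class <- vapply(variants$cds, classify_variant, "",
                           reference = reference,
                           cys_positions = cys_positions, USE.NAMES = FALSE)
  variants
}

#' Greedy incremental clustering at an identity threshold
#'
#' Variants are processed by (length descending, lexicographic); the first
#' founds a cluster and becomes its representative.  Each subsequent variant
#' joins the representative with the highest identity at or above the
#' threshold (best-representative rule, order-stable), or founds a new
#' cluster.  Identity is [pairwise_identity()] (identical positions /
#' alignment length, terminal gaps excluded).
#'
#' @param variants data.frame from [dereplicate()] (optionally classified).
#' @param threshold identity cut-off in (0, 1]; default 0.95.
#' @return List with `clusters` (data.frame: cluster_id, representative,
#'   n_members, members) and `assignment` (named vector variant -> cluster).
#' @export
cluster_greedy <- function(variants, threshold = 0.95) {
  stopifnot(threshold > 0, threshold <= 1)
  v <- variants[order(-nchar(variants$cds), variants$cds), , drop = FALSE]
  reps <- character(0)      # representative cds
  rep_ids <- character(0)
  members <- list()
  assignment <- character(0)
  for (i in seq_len(nrow(v))) {
    id <- v$variant_id[i]; cds <- v$cds[i]
    best <- 0; best_k <- 0L
    for (k in seq_along(reps)) {
      idy <- pairwise_identity(cds, reps[k])
      if (idy > best) { best <- idy; best_k <- k }
    }
    if (best_k > 0L && best >= threshold) {
      members[[best_k]] <- c(members[[best_k]], id)
      assignment[[id]] <- rep_ids[best_k]
    } else {
      reps <- c(reps, cds)
      rep_ids <- c(rep_ids, id)
      members[[length(reps)]] <- id
      assignment[[id]] <- id
    }
  }
  cl <- data.frame(
    cluster_id = sprintf("cl%02d", seq_along(reps)),
    representative = rep_ids,
    n_members = vapply(members, length, 0L),
    members = vapply(members, paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  assignment <- stats::setNames(
    cl$cluster_id[match(assignment, cl$representative)], names(assignment))
  list(clusters = cl, assignment = assignment)
}

#' Per-codon-column consensus of a cluster
#'
#' The consensus codon of a column is the strict-plurality codon among the
#' cluster's members; ties yield the ambiguous codon `NNN`, translated `X`.
#' Columns that are all-gap within the cluster are removed; consensus STOP
#' codons translate to `*`.
#'
#' @param member_ids variant ids of the cluster's members.
#' @param alignment codon alignment matrix from [align_family()] whose
#'   rownames cover `member_ids`.
#' @return List with `cds` (consensus nucleotide string, `NNN` for
#'   ambiguous codons) and `peptide` (with `X` for ambiguity, `-` for
#'   gap-majority columns).
#' @export
cluster_consensus <- function(member_ids, alignment) {
  if (length(member_ids) == 0L) stop("empty cluster")
  miss <- setdiff(member_ids, rownames(alignment))
  if (length(miss)) stop("members missing from alignment: ",
                         paste(miss, collapse = ","))
  sub <- alignment[member_ids, , drop = FALSE]
  cods <- character(0); aas <- character(0)
  for (j in seq_len(ncol(sub))) {
    tab <- sort(table(sub[, j]), decreasing = TRUE)
    if (length(tab) == 1L && names(tab)[1] == GAP_CODON) next  # all-gap
    if (length(tab) > 1L && tab[1] == tab[2]) {
      cods <- c(cods, "NNN"); aas <- c(aas, "X")
    } else {
      top <- names(tab)[1]
      cods <- c(cods, top)
      aas <- c(aas, if (top == GAP_CODON) "-" else codon_aa(top))
    }
  }
  list(cds = paste(cods, collapse = ""), peptide = paste(aas, collapse = ""))
}

#' Presence/absence variation matrices
#'
#' Builds the variant-level boolean presence matrix (rows = variants,
#' columns = individuals) and, when a clustering is supplied, the
#' cluster-level matrix (cluster presence = union of member presence).
#' Rows are ordered by descending carrier frequency.
#'
#' @param variants data.frame from [dereplicate()].
#' @param individuals character vector of all individual ids (columns).
#' @param assignment optional named vector variant_id -> cluster_id.
#' @return List with `variant` (logical matrix) and `cluster` (logical
#'   matrix or NULL).
#' @export
build_pav <- function(variants, individuals, assignment = NULL) {
  carr <- strsplit(variants$carriers, ",")
  unknown <- setdiff(unlist(carr), individuals)
  if (length(unknown)) stop("unknown individual ids: ",
                            paste(unknown, collapse = ","))
  m <- matrix(FALSE, nrow(variants), length(individuals),
              dimnames = list(variants$variant_id, individuals))
  for (i in seq_len(nrow(variants))) m[i, carr[[i]]] <- TRUE
  m <- m[order(-rowSums(m), rownames(m)), , drop = FALSE]
  cl <- NULL
  if (!is.null(assignment)) {
    ids <- sort(unique(assignment))
    cl <- matrix(FALSE, length(ids), length(individuals),
                 dimnames = list(ids, individuals))
    for (v in rownames(m)) cl[assignment[[v]], ] <- cl[assignment[[v]], ] | m[v, ]
    cl <- cl[order(-rowSums(cl), rownames(cl)), , drop = FALSE]
  }
  list(variant = m, cluster = cl)
}

#' Summary statistics of a presence/absence matrix
#'
#' @param pav logical matrix, rows = variants or clusters, columns =
#'   individuals.
#' @return List: mean_per_individual, mean_private_per_individual,
#'   occupancy (per-row fraction of individuals), n_universal (rows present
#'   in every individual), n_private (rows with a single carrier).
#' @export
pav_stats <- function(pav) {
  if (nrow(pav) == 0L) stop("empty matrix")
  private_rows <- rowSums(pav) == 1L
  list(
    mean_per_individual = mean(colSums(pav)),
    mean_private_per_individual = mean(colSums(pav[private_rows, , drop = FALSE])),
    occupancy = rowMeans(pav),
    n_universal = sum(rowMeans(pav) == 1),
    n_private = sum(private_rows))
}
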