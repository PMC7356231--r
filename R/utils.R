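#' @importFrom Biostrings DNAString DNAStringSet AAString AAStringSet
#' @importFrom Biostrings reverseComplement translate writeXStringSet
#' @importFrom Biostrings readDNAStringSet pairwiseAlignment matchPattern
#' @importFrom Biostrings nucleotideSubstitutionMatrix nmatch pattern subject
#' @importFrom Biostrings score GENETIC_CODE
#' @importFrom methods is
#' @importFrom stats setNames
NULL

NUCS <- c("A", "C", "G", "T")

# all 64 codons and their translations, in a fixed lexicographic order
codon_universe <- function() {
  cods <- as.vector(outer(outer(NUCS, NUCS, paste0), NUCS, paste0))
  sort(cods)
}

.codon_env <- new.env(parent = emptyenv())

codon_table <- function() {
  if (is.null(.codon_env$aa)) {
    cods <- codon_universe()
    .codon_env$aa <- setNames(as.character(Biostrings::GENETIC_CODE[cods]), cods)
  }
  .codon_env$aa
}

codon_aa <- function(codon) unname(codon_table()[codon])

is_stop_codon <- function(codon) codon_aa(codon) == "*"

#' Split a coding sequence into codons
#'
#' @param cds character scalar or `DNAString`; length must be a multiple of 3.
#' @return character vector of codons.
#' @keywords internal
split_codons <- function(cds) {
  cds <- as.character(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length not a multiple of 3")
  if (n == 0L) return(character(0))
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

translate_cds <- function(cds) {
  paste(codon_aa(split_codons(cds)), collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

random_dna <- function(n) paste(sample(NUCS, n, replace = TRUE), collapse = "")

# derive a stage-specific RNG seed from a master seed; keeps results < 2^31
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(k) * 7L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
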