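#' pKa tables for charge and isoelectric-point calculations
#'
#' Two dissociation-constant sets from the Isoelectric Point Calculator
#' (IPC) family of calibrations: `"IPC_protein"` (default) and
#' `"IPC_peptide"`.  A custom table may be supplied as a named numeric
#' vector with entries `NH2`, `COOH`, `C`, `D`, `E`, `H`, `K`, `R`, `Y`.
#'
#' @param name `"IPC_protein"` or `"IPC_peptide"`.
#' @return Named numeric vector of pKa values.
#' @export
pka_table <- function(name = c("IPC_protein", "IPC_peptide")) {
  name <- match.arg(name)
  tab <- switch(name,
    IPC_protein = c(NH2 = 9.094, COOH = 2.869, C = 7.555, D = 3.872,
                    E = 4.412, H = 5.637, K = 9.052, R = 11.84, Y = 10.85),
    IPC_peptide = c(NH2 = 9.564, COOH = 2.383, C = 8.297, D = 3.887,
                    E = 4.317, H = 6.018, K = 10.517, R = 12.503, Y = 10.071))
  validate_pka(tab)
}

validate_pka <- function(tab) {
  need <- c("NH2", "COOH", "C", "D", "E", "H", "K", "R", "Y")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("pKa table missing entries: ", paste(miss, collapse = ","))
  if (any(tab <= 0 | tab >= 14)) stop("pKa values must lie in (0, 14)")
  tab
}

# residue counts relevant to charge; X and other unknowns are ignored
ionizable_counts <- function(peptide) {
  aa <- strsplit(toupper(peptide), "")[[1]]
  if (any(aa == "X")) warning("'X' residues carry no charge")
  vapply(c("C", "D", "E", "H", "K", "R", "Y"), function(r) sum(aa == r), 0L)
}

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch sum: basic groups (N-terminus, K, R, H) contribute
#' `1 / (1 + 10^(pH - pKa))`, acidic groups (C-terminus, D, E, C, Y)
#' contribute `-1 / (1 + 10^(pKa - pH))`.  Cysteines are treated as free
#' thiols (no disulfide masking).
#'
#' @param peptide amino-acid string; `X` is ignored with a warning.
#' @param pH pH value.
#' @param pka named pKa vector, see [pka_table()].
#' @param termini include the free N/C termini (default TRUE).
#' @return Net charge in elementary charges.
#' @export
net_charge <- function(peptide, pH = 7.4, pka = pka_table(), termini = TRUE) {
  if (!nzchar(peptide)) stop("empty peptide")
  pka <- validate_pka(pka)
  cnt <- ionizable_counts(peptide)
  basic <- function(pk) 1 / (1 + 10^(pH - pk))
  acidic <- function(pk) 1 / (1 + 10^(pk - pH))
  q <- cnt[["K"]] * basic(pka[["K"]]) +
    cnt[["R"]] * basic(pka[["R"]]) +
    cnt[["H"]] * basic(pka[["H"]]) -
    cnt[["D"]] * acidic(pka[["D"]]) -
    cnt[["E"]] * acidic(pka[["E"]]) -
    cnt[["C"]] * acidic(pka[["C"]]) -
    cnt[["Y"]] * acidic(pka[["Y"]])
  if (termini) q <- q + basic(pka[["NH2"]]) - acidic(pka[["COOH"]])
  unname(q)
}

#' Isoelectric point by bisection
#'
#' Finds the pH at which [net_charge()] is zero.  The charge function is
#' strictly decreasing in pH for any peptide with at least one ionizable
#' group, so the root is unique; bisection on `[0, 14]` stops when
#' `|Q| < tol`.
#'
#' @inheritParams net_charge
#' @param tol charge tolerance at the root (default 1e-3).
#' @return pI in pH units.
#' @export
isoelectric_point <- function(peptide, pka = pka_table(), tol = 1e-3,
                              termini = TRUE) {
  pka <- validate_pka(pka)
  q <- function(ph) suppressWarnings(net_charge(peptide, ph, pka, termini))
  lo <- 0; hi <- 14
  qlo <- q(lo); qhi <- q(hi)
  if (qlo <= 0 || qhi >= 0) stop("pI undefined: peptide lacks ionizable groups of both signs")
  mid <- 7
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (q(mid) > 0) lo <- mid else hi <- mid
  }
  if (abs(q(mid)) >= tol) {
    warning("charge at the bisection root exceeds tolerance")
  }
  mid
}

AA_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

#' Average molecular weight of a peptide
#'
#' Sum of average residue masses plus one water; `X` contributes the
#' generic 110 Da residue mass.
#'
#' @param peptide amino-acid string.
#' @return Mass in Daltons.
#' @export
molecular_weight <- function(peptide) {
  aa <- strsplit(toupper(peptide), "")[[1]]
  m <- AA_MASS[aa]
  m[is.na(m)] <- 110
  sum(m) + 18.0153
}

#' Sliding-window isoelectric-point profile
#'
#' pI of every `window`-residue subsequence, each treated as a free peptide
#' (charged termini by default).  Windows in which the pI is undefined (no
#' ionizable group of one sign) yield `NA`.
#'
#' @inheritParams net_charge
#' @param window window width in residues (default 15).
#' @return Numeric vector of length `max(L - window + 1, 0)`.
#' @export
sliding_pi <- function(peptide, window = 15L, pka = pka_table(),
                       termini = TRUE) {
  if (window < 2L) stop("window must be >= 2")
  L <- nchar(peptide)
  if (L < window) return(numeric(0))
  vapply(seq_len(L - window + 1L), function(i) {
    sub <- substr(peptide, i, i + window - 1L)
    tryCatch(isoelectric_point(sub, pka, termini = termini),
             error = function(e) NA_real_)
  }, 0)
}

#' Mature-peptide boundaries on a precursor
#'
#' Globally aligns the precursor to the reference mature peptide; the mature
#' interval starts at the precursor position aligned to the reference's
#' first residue and ends at the position aligned to its conserved
#' C-terminal arginine (inclusive).  If the precursor residue at the end
#' column is not Arg a boundary warning is raised and the reference column
#' is used regardless.
#'
#' @param precursor precursor peptide string.
#' @param reference reference mature peptide.
#' @return Integer vector `c(start, end)`, 1-based inclusive on the
#'   precursor.
#' @export
mature_boundaries <- function(precursor, reference = reference_mature_peptide()) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(precursor), Biostrings::AAString(reference),
    type = "global", substitutionMatrix = blosum62(),
    gapOpening = 10, gapExtension = 0.5)
  pat <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  rp <- 0L; pp <- 0L
  start <- NA_integer_; end <- NA_integer_; end_res <- NA_character_
  for (k in seq_along(sub)) {
    if (pat[k] != "-") pp <- pp + 1L
    if (sub[k] != "-") {
      rp <- rp + 1L
      if (rp == 1L) start <- max(pp, 1L)
      if (rp == nchar(reference)) { end <- pp; end_res <- pat[k] }
    }
  }
  if (is.na(end_res) || end_res != "R") {
    warning("no arginine at the reference C-terminal column; using the aligned column")
  }
  c(start = start, end = end)
}

#' Biophysical profile of a mature peptide
#'
#' @inheritParams net_charge
#' @param window sliding-window width.
#' @return List: peptide, pI, charge (at `pH`), mw, sliding (pI series).
#' @export
peptide_profile <- function(peptide, pH = 7.4, pka = pka_table(),
                            window = 15L) {
  list(peptide = peptide,
       pI = isoelectric_point(peptide, pka),
       charge = net_charge(peptide, pH, pka),
       mw = molecular_weight(peptide),
       sliding = sliding_pi(peptide, window, pka))
}
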