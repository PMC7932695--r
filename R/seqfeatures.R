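#' @include AllClasses.R
NULL

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## accept an AAString / AAStringSet element / plain character; return a
## validated uppercase character scalar over the 20 canonical letters
.asProtein <- function(protein) {
  p <- toupper(as.character(protein))
  if (length(p) != 1 || !nzchar(p)) stop("protein sequence must be non-empty")
  res <- strsplit(p, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(res), .AA20)
  if (length(bad))
    stop("non-canonical residue(s): ", paste(bad, collapse = ", "))
  p
}

#' Translate a DNA coding sequence to protein
#'
#' Standard genetic code; the input length must be a multiple of 3 and use
#' only A/C/G/T (case-insensitive). A single terminal stop codon is
#' stripped; an internal stop codon is an error, as are invalid length or
#' characters (each reported distinctly).
#'
#' @param dna Character scalar or [Biostrings::DNAString].
#' @return A [Biostrings::AAString] protein sequence.
#' @examples
#' as.character(translateDna("ATGGCT"))  # "MA"
#' @export
translateDna <- function(dna) {
  d <- toupper(as.character(dna))
  if (length(d) != 1 || !nzchar(d)) stop("DNA sequence must be non-empty")
  if (nchar(d) %% 3 != 0)
    stop("DNA length ", nchar(d), " is not a multiple of 3")
  if (grepl("[^ACGT]", d))
    stop("invalid DNA character(s): ",
         paste(unique(strsplit(gsub("[ACGT]", "", d), "")[[1]]),
               collapse = ", "))
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(d)))
  if (endsWith(aa, "*")) aa <- substr(aa, 1, nchar(aa) - 1)
  star <- regexpr("*", aa, fixed = TRUE)
  if (star > 0)
    stop("internal stop codon at codon ", star)
  Biostrings::AAString(aa)
}

#' Bjellqvist-style pKa table
#'
#' The classic ExPASy side-chain pKa values with constant termini pKa
#' (N-terminus 7.5, C-terminus 3.55). This table reproduces the printed
#' isoelectric points of the Cox15 IDR variants to within 0.05 pH units;
#' supply a different table to [isoelectricPoint()] to change convention.
#'
#' @return Named list with `Nterm`, `Cterm`, and side-chain entries
#'   `D`, `E`, `C`, `Y`, `H`, `K`, `R`.
#' @export
bjellqvistPka <- function() {
  list(Nterm = 7.50, Cterm = 3.55,
       D = 4.05, E = 4.45, C = 9.00, Y = 10.00,
       H = 5.98, K = 10.00, R = 12.00)
}

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch sum over the free N-terminus and basic side
#' chains (H, K, R) minus the free C-terminus and acidic/ionizable side
#' chains (D, E, C, Y). Strictly decreasing in pH for every sequence,
#' which guarantees a unique isoelectric point.
#'
#' @param protein Protein sequence (character or AAString).
#' @param pH pH value(s).
#' @param pKa pKa table as from [bjellqvistPka()].
#' @return Net charge (vectorized over `pH`).
#' @export
.chargeFromCounts <- function(cnt, ph, pKa) {
  pos <- 1 / (1 + 10^(ph - pKa$Nterm)) +
    sum(vapply(c("H", "K", "R"), function(a)
      cnt[[a]] / (1 + 10^(ph - pKa[[a]])), 0))
  neg <- 1 / (1 + 10^(pKa$Cterm - ph)) +
    sum(vapply(c("D", "E", "C", "Y"), function(a)
      cnt[[a]] / (1 + 10^(pKa[[a]] - ph)), 0))
  pos - neg
}

.residueCounts <- function(p) {
  res <- strsplit(p, "", fixed = TRUE)[[1]]
  as.list(table(factor(res, levels = .AA20)))
}

netCharge <- function(protein, pH, pKa = bjellqvistPka()) {
  cnt <- .residueCounts(.asProtein(protein))
  vapply(pH, function(ph) .chargeFromCounts(cnt, ph, pKa), 0)
}

#' Isoelectric point by bisection
#'
#' The pH in \[0, 14\] at which [netCharge()] is zero, found by bisection
#' to within 0.005 pH units (the net charge at the returned pI has
#' magnitude below 0.01 for ordinary peptides).
#'
#' @inheritParams netCharge
#' @return The pI.
#' @examples
#' isoelectricPoint("KRKRKR") > isoelectricPoint("DEDEDE")
#' @export
isoelectricPoint <- function(protein, pKa = bjellqvistPka()) {
  cnt <- .residueCounts(.asProtein(protein))
  lo <- 0; hi <- 14
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (.chargeFromCounts(cnt, mid, pKa) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Kyte-Doolittle hydropathy scale
#'
#' @return Named numeric vector over the 20 canonical residues.
#' @export
kyteDoolittle <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
    G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
    P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
}

#' Mean hydropathy of a protein sequence
#'
#' Arithmetic mean of a per-residue hydropathy scale (Kyte-Doolittle by
#' default) over the sequence; invariant under residue permutation.
#'
#' @inheritParams netCharge
#' @param scale Named per-residue scale covering all 20 residues.
#' @return Mean scale value.
#' @examples
#' meanHydropathy("AR")  # (1.8 - 4.5) / 2
#' @export
meanHydropathy <- function(protein, scale = kyteDoolittle()) {
  p <- .asProtein(protein)
  stopifnot(all(.AA20 %in% names(scale)))
  res <- strsplit(p, "", fixed = TRUE)[[1]]
  mean(scale[res])
}

#' Fraction of residues belonging to a residue set
#'
#' @inheritParams netCharge
#' @param residues Residue set, e.g. `"KR"` or `c("K", "R")`.
#' @return Fraction in \[0, 1\].
#' @examples
#' compositionFraction("QQAQ", "Q")  # 0.75
#' @export
compositionFraction <- function(protein, residues) {
  p <- .asProtein(protein)
  set <- unique(strsplit(paste(residues, collapse = ""), "",
                         fixed = TRUE)[[1]])
  res <- strsplit(p, "", fixed = TRUE)[[1]]
  mean(res %in% set)
}

## consensus pattern -> regular expression: positions separated by "-",
## alternatives within a position by "/", "." or "x" is any residue.
## A pattern without separators is matched literally.
.consensusRegex <- function(pattern) {
  if (!nzchar(pattern)) stop("empty motif pattern")
  if (!grepl("[-/]", pattern)) return(list(re = pattern, fixed = TRUE))
  pos <- strsplit(pattern, "-", fixed = TRUE)[[1]]
  re <- vapply(pos, function(p) {
    alts <- strsplit(p, "/", fixed = TRUE)[[1]]
    if (length(alts) == 1 && alts %in% c(".", "x", "X")) return(".")
    if (length(alts) == 1) return(alts)
    paste0("[", paste(alts, collapse = ""), "]")
  }, "")
  list(re = paste(re, collapse = ""), fixed = FALSE)
}

#' Count non-overlapping motif matches
#'
#' Counts matches of a motif scanning left to right without overlap. The
#' pattern is either a literal substring (`"RGG"`) or a consensus with
#' positions separated by `-` and alternatives by `/` (`"S/T-P"` matches
#' serine or threonine followed by proline; `.` or `x` is any residue).
#'
#' @inheritParams netCharge
#' @param pattern Motif pattern.
#' @return Integer count.
#' @examples
#' motifCount("RGGRGG", "RGG")   # 2
#' motifCount("SPATP", "S/T-P")  # 2
#' @export
motifCount <- function(protein, pattern) {
  p <- .asProtein(protein)
  cx <- .consensusRegex(pattern)
  m <- gregexpr(cx$re, p, fixed = cx$fixed)[[1]]
  if (m[1] == -1) 0L else length(m)
}

#' Apply a residue substitution map
#'
#' Replaces every occurrence of each map key with its value, e.g.
#' `c(R = "E")` performs the arginine-to-glutamate mutation that collapses
#' a high isoelectric point while leaving hydropathy almost unchanged.
#'
#' @inheritParams netCharge
#' @param map Named character vector: `names(map)` are replaced by the
#'   corresponding values.
#' @return The mutated sequence as [Biostrings::AAString].
#' @export
substituteResidues <- function(protein, map) {
  p <- .asProtein(protein)
  stopifnot(length(map) >= 1, !is.null(names(map)),
            all(nchar(names(map)) == 1), all(nchar(map) == 1))
  Biostrings::AAString(chartr(paste(names(map), collapse = ""),
                              paste(map, collapse = ""), p))
}

#' Standardize matrix columns to zero mean and unit variance
#'
#' Sample (n-1) variance; a constant column is an error naming the column.
#'
#' @param x Numeric matrix with at least 2 rows.
#' @return Matrix of the same shape with each column standardized.
#' @export
zscoreColumns <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 rows to standardize")
  sdv <- apply(x, 2, sd)
  if (any(sdv == 0)) {
    bad <- colnames(x)[which(sdv == 0)[1]]
    if (is.null(bad)) bad <- which(sdv == 0)[1]
    stop("constant column cannot be standardized: ", bad)
  }
  scale(x)[, , drop = FALSE]
}

#' Z-score of an observed statistic against a simulated null
#'
#' `(observed - mean(null)) / sd(null)` with the sample (n-1) standard
#' deviation. Negative values mean the observed statistic is below the
#' null expectation, positive above.
#'
#' @param observed Observed scalar statistic.
#' @param nullValues Numeric vector of null draws (at least 2, nonzero
#'   spread).
#' @return The Z-score.
#' @export
signatureZscore <- function(observed, nullValues) {
  stopifnot(length(observed) == 1, is.finite(observed),
            length(nullValues) >= 2)
  s <- sd(nullValues)
  if (s == 0) stop("null distribution has zero spread")
  (observed - mean(nullValues)) / s
}
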