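#' @include seqfeatures.R
NULL

#' Default molecular-feature catalog (82 features)
#'
#' A data-driven registry of sequence-distributed molecular features of
#' disordered regions: per-residue composition fractions, physicochemical
#' class fractions, the mean Kyte-Doolittle hydropathy, global properties
#' (isoelectric point, net charge at pH 7, length), di- and tri-residue
#' repeat counts, and consensus short-linear-motif counts (CDK, CKII,
#' Mec1/Tel1-type S/T-Q, PKA-type, KEN and destruction-box cores, NLS
#' core, RGG/RG and related repeats). The default catalog has 82 entries;
#' users can extend or replace it -- every downstream computation takes the
#' catalog as an argument.
#'
#' @return data.frame with columns `name`, `kind`
#'   (`composition` / `scale-mean` / `motif-count` / `global`), and
#'   `parameter` (residue set, scale name, motif consensus, or global
#'   property name).
#' @seealso [computeFeatures()], [signatureColumnNames()]
#' @export
featureCatalog <- function() {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  comp1 <- data.frame(name = paste0("frac_", aa), kind = "composition",
                      parameter = aa)
  classes <- c(positive = "KR", negative = "DE", charged = "DEHKR",
               aromatic = "FWY", aliphatic = "ILV", polar = "NQST",
               hydrophobic = "ACFILMVW", disorder_promoting = "AEGKPQRS",
               order_promoting = "CFILMNVWY", GP = "GP", QN = "QN",
               ST = "ST")
  comp2 <- data.frame(name = paste0("frac_", names(classes)),
                      kind = "composition", parameter = unname(classes))
  scales <- data.frame(name = "kd_hydropathy", kind = "scale-mean",
                       parameter = "kyte_doolittle")
  globals <- data.frame(name = c("pI", "net_charge", "length"),
                        kind = "global",
                        parameter = c("pI", "net_charge", "length"))
  direp <- data.frame(name = paste0("rep_", aa, aa), kind = "motif-count",
                      parameter = paste0(aa, aa))
  tri <- c("QQQ", "NNN", "SSS", "GGG", "KKK", "EEE", "DDD", "PPP",
           "AAA", "TTT")
  trirep <- data.frame(name = paste0("rep_", tri), kind = "motif-count",
                       parameter = tri)
  slims <- c(cdk_min       = "S/T-P",
             cdk_full      = "S/T-P-.-K/R",
             ckii          = "S/T-.-.-D/E",
             stq           = "S/T-Q",
             pka           = "R-.-.-S",
             basophilic    = "R/K-R/K-.-S/T",
             ken_box       = "KEN",
             d_box         = "R-.-.-L",
             nls_core      = "K-K/R-.-K/R",
             ppxy          = "P-P-.-Y",
             polyproline   = "P-.-.-P",
             rgg           = "RGG",
             rg            = "RG",
             fg            = "FG",
             sr            = "SR",
             kap_repeat    = "K/A/P-K/A/P-K/A/P")
  slimdf <- data.frame(name = paste0("motif_", names(slims)),
                       kind = "motif-count", parameter = unname(slims))
  rbind(comp1, comp2, scales, globals, direp, trirep, slimdf)
}

.GLOBAL_FEATURES <- c("pI", "net_charge", "length")

## evaluate one catalog entry on one validated sequence
.evalFeature <- function(p, kind, parameter) {
  switch(kind,
    "composition" = compositionFraction(p, parameter),
    "scale-mean"  = {
      stopifnot(parameter == "kyte_doolittle")
      meanHydropathy(p)
    },
    "motif-count" = as.numeric(motifCount(p, parameter)),
    "global" = switch(parameter,
      "pI" = isoelectricPoint(p),
      "net_charge" = netCharge(p, 7.0),
      "length" = nchar(p),
      stop("unknown global feature: ", parameter)),
    stop("unknown feature kind: ", kind))
}

#' Compute catalog features for a set of protein sequences
#'
#' @param seqs Named character vector or [Biostrings::AAStringSet] of
#'   protein sequences.
#' @param catalog Feature catalog (default [featureCatalog()]).
#' @return Numeric matrix, sequences x features.
#' @examples
#' f <- computeFeatures(c(idr1 = "MKKRRSPQQ"))
#' f[, c("frac_positive", "pI")]
#' @export
computeFeatures <- function(seqs, catalog = featureCatalog()) {
  nm <- names(seqs)
  seqs <- vapply(as.character(seqs), .asProtein, "", USE.NAMES = FALSE)
  names(seqs) <- nm
  stopifnot(all(c("name", "kind", "parameter") %in% names(catalog)),
            !anyDuplicated(catalog$name))
  out <- matrix(NA_real_, length(seqs), nrow(catalog),
                dimnames = list(names(seqs), catalog$name))
  for (j in seq_len(nrow(catalog)))
    out[, j] <- vapply(seqs, .evalFeature, 0,
                       kind = catalog$kind[j],
                       parameter = catalog$parameter[j])
  out
}

#' Column names of the evolutionary-signature layout
#'
#' Evolutionary signatures summarize each molecular feature by its mean
#' and its log variance across a set of orthologous IDRs; the 82-feature
#' default catalog therefore yields 164 signature columns.
#'
#' @param catalog Feature catalog (default [featureCatalog()]).
#' @return Character vector `mean_<feature>` then `logvar_<feature>`.
#' @export
signatureColumnNames <- function(catalog = featureCatalog()) {
  c(paste0("mean_", catalog$name), paste0("logvar_", catalog$name))
}

#' Mean / log-variance summary of features over an ortholog set
#'
#' Computes the catalog features for each orthologous sequence and returns
#' the per-feature mean and log sample variance (variance floored at
#' `varFloor` so invariant features stay finite), in the
#' [signatureColumnNames()] layout. Dividing each summary by the spread of
#' the same statistic under simulated null evolution ([signatureZscore()])
#' turns these into evolutionary-signature Z-scores.
#'
#' @param seqs Ortholog set: named character vector or
#'   [Biostrings::AAStringSet] (at least 2 sequences).
#' @param catalog Feature catalog.
#' @param varFloor Floor for the variance before taking logs
#'   (default 1e-8).
#' @return Named numeric vector of length `2 * nrow(catalog)`.
#' @export
orthologSignature <- function(seqs, catalog = featureCatalog(),
                              varFloor = 1e-8) {
  f <- computeFeatures(seqs, catalog)
  if (nrow(f) < 2) stop("an ortholog set needs at least 2 sequences")
  mu <- colMeans(f)
  lv <- log(pmax(apply(f, 2, var), varFloor))
  setNames(c(mu, lv), signatureColumnNames(catalog))
}
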