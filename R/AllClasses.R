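#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## IdrFeatureTable
## ---------------------------------------------------------------------------

#' Per-IDR molecular feature table
#'
#' Rows are IDRs grouped by protein, columns are molecular features (for
#' example the 164 evolutionary-signature Z-scores, or 82 single-species
#' features scaled to zero mean and unit variance). Each IDR carries its
#' protein identifier, its ordinal index within the protein, and optional
#' 1-based inclusive amino-acid coordinates.
#'
#' @slot features numeric matrix, IDR rows x feature columns; rownames are
#'   IDR identifiers (`"PROTEIN|start-end"` or `"PROTEIN|j"`).
#' @slot proteinId character, protein of each row.
#' @slot idrIndex integer, ordinal index j >= 1 of the IDR within its protein.
#' @slot idrStart,idrEnd integer, 1-based inclusive coordinates (NA when the
#'   table is coordinate-free).
#'
#' @seealso [readFeatureTable()], [fitFaidr()]
#' @export
setClass("IdrFeatureTable",
  representation(
    features  = "matrix",
    proteinId = "character",
    idrIndex  = "integer",
    idrStart  = "integer",
    idrEnd    = "integer"
  )
)

setValidity("IdrFeatureTable", function(object) {
  msg <- character()
  n <- nrow(object@features)
  if (!is.numeric(object@features))
    msg <- c(msg, "feature matrix must be numeric")
  if (any(!is.finite(object@features)))
    msg <- c(msg, "feature matrix contains non-finite values")
  if (length(object@proteinId) != n || length(object@idrIndex) != n ||
      length(object@idrStart) != n || length(object@idrEnd) != n)
    msg <- c(msg, "per-IDR slots must have one entry per feature row")
  if (is.null(colnames(object@features)) ||
      anyDuplicated(colnames(object@features)))
    msg <- c(msg, "feature names must be present and unique")
  if (is.null(rownames(object@features)) ||
      anyDuplicated(rownames(object@features)))
    msg <- c(msg, "IDR identifiers (rownames) must be present and unique")
  if (n > 0) {
    if (anyDuplicated(paste(object@proteinId, object@idrIndex)))
      msg <- c(msg, "idrIndex must be unique within each protein")
    if (any(object@idrIndex < 1L))
      msg <- c(msg, "idrIndex must be >= 1")
    has <- !is.na(object@idrStart)
    if (any(has != !is.na(object@idrEnd)))
      msg <- c(msg, "idrStart and idrEnd must be NA together")
    if (any(has) && any(object@idrStart[has] < 1L |
                        object@idrStart[has] > object@idrEnd[has]))
      msg <- c(msg, "coordinates must satisfy 1 <= start <= end")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an IdrFeatureTable
#'
#' @param features numeric matrix (IDRs x features) with unique column names.
#' @param proteinId character vector, protein of each row.
#' @param start,end optional 1-based inclusive amino-acid coordinates.
#' @param idrIndex optional ordinal index within protein; defaults to the
#'   order of appearance.
#' @param idrId optional row identifiers; defaults to
#'   `"PROTEIN|start-end"` when coordinates are given, else `"PROTEIN|j"`.
#' @return An [IdrFeatureTable-class].
#' @examples
#' z <- matrix(rnorm(6), 3, 2, dimnames = list(NULL, c("f1", "f2")))
#' tab <- IdrFeatureTable(z, proteinId = c("A", "A", "B"))
#' idrCounts(tab)
#' @export
IdrFeatureTable <- function(features, proteinId, start = NULL, end = NULL,
                            idrIndex = NULL, idrId = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  n <- nrow(features)
  proteinId <- as.character(proteinId)
  if (is.null(idrIndex)) {
    idrIndex <- as.integer(stats::ave(seq_len(n), proteinId, FUN = seq_along))
  }
  idrIndex <- as.integer(idrIndex)
  start <- if (is.null(start)) rep(NA_integer_, n) else as.integer(start)
  end <- if (is.null(end)) rep(NA_integer_, n) else as.integer(end)
  if (is.null(idrId)) {
    idrId <- ifelse(is.na(start),
                    paste0(proteinId, "|", idrIndex),
                    paste0(proteinId, "|", start, "-", end))
  }
  rownames(features) <- idrId
  new("IdrFeatureTable", features = features, proteinId = proteinId,
      idrIndex = idrIndex, idrStart = start, idrEnd = end)
}

#' @rdname accessors
#' @export
setMethod("featureMatrix", "IdrFeatureTable", function(x, ...) x@features)

#' @rdname accessors
#' @export
setMethod("featureNames", "IdrFeatureTable", function(x, ...) colnames(x@features))

#' @rdname accessors
#' @export
setMethod("proteinIds", "IdrFeatureTable", function(x, ...) unique(x@proteinId))

#' @rdname accessors
#' @export
setMethod("idrIds", "IdrFeatureTable", function(x, ...) rownames(x@features))

#' @rdname accessors
#' @export
setMethod("idrProtein", "IdrFeatureTable", function(x, ...)
  setNames(x@proteinId, rownames(x@features)))

#' @rdname accessors
#' @export
setMethod("idrCounts", "IdrFeatureTable", function(x, ...) {
  tab <- table(factor(x@proteinId, levels = unique(x@proteinId)))
  setNames(as.integer(tab), names(tab))
})

#' @rdname accessors
#' @export
setMethod("idrCoordinates", "IdrFeatureTable", function(x, ...)
  data.frame(idr_id = rownames(x@features), protein_id = x@proteinId,
             idr_index = x@idrIndex, start = x@idrStart, end = x@idrEnd,
             stringsAsFactors = FALSE))

#' @export
setMethod("dim", "IdrFeatureTable", function(x) dim(x@features))

#' Subset an IdrFeatureTable by IDR rows
#'
#' @param x An [IdrFeatureTable-class].
#' @param i Row indices (integer, logical, or IDR-id character).
#' @param j,...,drop Ignored (columns are never dropped).
#' @export
setMethod("[", "IdrFeatureTable", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, rownames(x@features))
  if (is.logical(i)) i <- which(i)
  new("IdrFeatureTable",
      features  = x@features[i, , drop = FALSE],
      proteinId = x@proteinId[i],
      idrIndex  = x@idrIndex[i],
      idrStart  = x@idrStart[i],
      idrEnd    = x@idrEnd[i])
})

#' Subset a feature table to a set of proteins
#'
#' Keeps every IDR row whose protein is in `proteins`, preserving row order.
#'
#' @param x An [IdrFeatureTable-class].
#' @param proteins character vector of protein identifiers.
#' @return An [IdrFeatureTable-class].
#' @export
subsetByProteins <- function(x, proteins) {
  stopifnot(is(x, "IdrFeatureTable"))
  x[x@proteinId %in% proteins]
}

setMethod("show", "IdrFeatureTable", function(object) {
  r <- idrCounts(object)
  cat("IdrFeatureTable:", nrow(object@features), "IDRs in", length(r),
      "proteins,", ncol(object@features), "features\n")
  cat("  IDRs per protein: ", paste(range(r), collapse = "-"),
      " (mean ", round(mean(r), 2), ")\n", sep = "")
  cat("  features: ", paste(head(colnames(object@features), 4), collapse = ", "),
      if (ncol(object@features) > 4) ", ..." else "", "\n", sep = "")
})

## ---------------------------------------------------------------------------
## AnnotationTable
## ---------------------------------------------------------------------------

#' Protein-level binary annotation table
#'
#' A proteins x functions 0/1 matrix: entry (i, f) is 1 when protein i is
#' annotated with function f.
#'
#' @slot labels integer 0/1 matrix; rownames are protein ids, colnames are
#'   function names.
#' @seealso [readAnnotationTable()], [fitFaidr()]
#' @export
setClass("AnnotationTable", representation(labels = "matrix"))

setValidity("AnnotationTable", function(object) {
  msg <- character()
  if (!all(object@labels %in% c(0L, 1L)))
    msg <- c(msg, "labels must be 0/1")
  if (is.null(rownames(object@labels)) || anyDuplicated(rownames(object@labels)))
    msg <- c(msg, "protein ids (rownames) must be present and unique")
  if (is.null(colnames(object@labels)) || anyDuplicated(colnames(object@labels)))
    msg <- c(msg, "function names (colnames) must be present and unique")
  if (length(msg)) msg else TRUE
})

#' Construct an AnnotationTable
#'
#' @param labels 0/1 matrix with protein rownames and function colnames.
#' @return An [AnnotationTable-class].
#' @export
AnnotationTable <- function(labels) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  new("AnnotationTable", labels = labels)
}

#' @rdname accessors
#' @export
setMethod("annotationMatrix", "AnnotationTable", function(x, ...) x@labels)

#' @rdname accessors
#' @export
setMethod("functionNames", "AnnotationTable", function(x, ...) colnames(x@labels))

#' @rdname accessors
#' @export
setMethod("proteinIds", "AnnotationTable", function(x, ...) rownames(x@labels))

#' @export
setMethod("dim", "AnnotationTable", function(x) dim(x@labels))

setMethod("show", "AnnotationTable", function(object) {
  cat("AnnotationTable:", nrow(object@labels), "proteins x",
      ncol(object@labels), "functions\n")
  pos <- colSums(object@labels)
  cat("  positives per function: ", paste(range(pos), collapse = "-"), "\n",
      sep = "")
})

## ---------------------------------------------------------------------------
## FaidrFit
## ---------------------------------------------------------------------------

#' Fitted multiple-instance logistic model for one function
#'
#' Holds the sparse coefficient vector b, the unpenalized intercept, the
#' final per-IDR responsibilities (posterior probability that the IDR
#' carries the function), the penalty hyperparameters, and the penalized
#' marginal log-likelihood trace over EM rounds.
#'
#' @slot functionName character scalar.
#' @slot coefficients numeric, named by feature.
#' @slot intercept numeric scalar.
#' @slot responsibilities numeric in (0, 1), named by IDR id, summing to 1
#'   within each protein.
#' @slot proteinId character, protein of each responsibility entry.
#' @slot lambda,alpha numeric penalty hyperparameters.
#' @slot nEmIterations integer, EM rounds performed.
#' @slot converged logical, whether the responsibility change fell below the
#'   EM tolerance before the iteration cap.
#' @slot objectiveTrace numeric, penalized marginal log-likelihood per EM
#'   round (element 1 is the value at initialization).
#' @slot control list, the [faidrControl()] used.
#' @seealso [fitFaidr()], [writeFit()]
#' @export
setClass("FaidrFit",
  representation(
    functionName     = "character",
    coefficients     = "numeric",
    intercept        = "numeric",
    responsibilities = "numeric",
    proteinId        = "character",
    lambda           = "numeric",
    alpha            = "numeric",
    nEmIterations    = "integer",
    converged        = "logical",
    objectiveTrace   = "numeric",
    control          = "list"
  )
)

setValidity("FaidrFit", function(object) {
  msg <- character()
  r <- object@responsibilities
  if (any(r < -1e-12 | r > 1 + 1e-12))
    msg <- c(msg, "responsibilities must lie in [0, 1]")
  if (length(r) != length(object@proteinId))
    msg <- c(msg, "responsibilities and proteinId must be parallel")
  if (length(r)) {
    sums <- tapply(r, object@proteinId, sum)
    if (any(abs(sums - 1) > 1e-10))
      msg <- c(msg, "responsibilities must sum to 1 within each protein (tol 1e-10)")
  }
  if (object@lambda <= 0) msg <- c(msg, "lambda must be > 0")
  if (object@alpha <= 0 || object@alpha > 1)
    msg <- c(msg, "alpha must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname fit-accessors
#' @export
setMethod("coef", "FaidrFit", function(object, ...) object@coefficients)

#' @rdname fit-accessors
#' @export
setMethod("intercept", "FaidrFit", function(object, ...) object@intercept)

#' @rdname fit-accessors
#' @export
setMethod("responsibilities", "FaidrFit", function(object, ...)
  setNames(object@responsibilities, names(object@responsibilities)))

#' @rdname accessors
#' @export
setMethod("featureNames", "FaidrFit", function(x, ...) names(x@coefficients))

setMethod("show", "FaidrFit", function(object) {
  nz <- sum(object@coefficients != 0)
  cat("FaidrFit for function '", object@functionName, "'\n", sep = "")
  cat("  lambda =", object@lambda, " alpha =", object@alpha, "\n")
  cat("  ", nz, " of ", length(object@coefficients),
      " features selected; intercept = ", signif(object@intercept, 4), "\n",
      sep = "")
  cat("  EM rounds: ", object@nEmIterations,
      if (object@converged) " (converged)" else " (iteration cap)", "\n",
      sep = "")
  tr <- object@objectiveTrace
  if (length(tr))
    cat("  penalized marginal log-likelihood: ",
        signif(tr[1], 6), " -> ", signif(tr[length(tr)], 6), "\n", sep = "")
})

## ---------------------------------------------------------------------------
## AssociationMatrix
## ---------------------------------------------------------------------------

#' Function x feature association matrix of t-statistics
#'
#' Wald t-statistics from unpenalized logistic refits on the features each
#' function's penalized fit selected; entries for unselected features are
#' exactly zero.
#'
#' @slot tstatistics numeric matrix, functions x features.
#' @slot selected logical matrix of the same shape: whether the feature had
#'   a nonzero penalized coefficient for that function.
#' @seealso [refitTstats()], [assembleMatrix()], [filterFeatures()]
#' @export
setClass("AssociationMatrix",
  representation(tstatistics = "matrix", selected = "matrix"))

setValidity("AssociationMatrix", function(object) {
  msg <- character()
  if (!identical(dim(object@tstatistics), dim(object@selected)))
    msg <- c(msg, "tstatistics and selected must have identical shape")
  if (any(!is.finite(object@tstatistics)))
    msg <- c(msg, "t-statistics must be finite")
  if (any(object@tstatistics[!object@selected] != 0))
    msg <- c(msg, "unselected entries must be exactly 0")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("functionNames", "AssociationMatrix", function(x, ...)
  rownames(x@tstatistics))

#' @rdname accessors
#' @export
setMethod("featureNames", "AssociationMatrix", function(x, ...)
  colnames(x@tstatistics))

#' Extract the t-statistic matrix
#'
#' @param x An [AssociationMatrix-class].
#' @return Numeric matrix, functions x features.
#' @export
tstatMatrix <- function(x) {
  stopifnot(is(x, "AssociationMatrix"))
  x@tstatistics
}

#' @export
setMethod("dim", "AssociationMatrix", function(x) dim(x@tstatistics))

setMethod("show", "AssociationMatrix", function(object) {
  cat("AssociationMatrix:", nrow(object@tstatistics), "functions x",
      ncol(object@tstatistics), "features\n")
  cat("  nonzero entries:", sum(object@tstatistics != 0), "\n")
})

## ---------------------------------------------------------------------------
## SyntheticIdrDataset
## ---------------------------------------------------------------------------

#' Synthetic multiple-instance dataset with known ground truth
#'
#' A generated feature table and single-function annotation table, together
#' with the true sparse coefficient vector, intercept, and the index of the
#' responsible IDR in every protein. Labels are generated only through the
#' responsible IDR's feature vector.
#'
#' @slot featureTable [IdrFeatureTable-class].
#' @slot annotations [AnnotationTable-class] with a single function column.
#' @slot trueCoefficients numeric, named by feature.
#' @slot trueIntercept numeric scalar.
#' @slot trueResponsible integer, named by protein: which IDR (ordinal)
#'   generated the label.
#' @slot spec list, the generator parameters (including the seed).
#' @seealso [generateSynthetic()], [recoveryReport()]
#' @export
setClass("SyntheticIdrDataset",
  representation(
    featureTable     = "IdrFeatureTable",
    annotations      = "AnnotationTable",
    trueCoefficients = "numeric",
    trueIntercept    = "numeric",
    trueResponsible  = "integer",
    spec             = "list"
  )
)

setValidity("SyntheticIdrDataset", function(object) {
  msg <- character()
  r <- idrCounts(object@featureTable)
  if (!identical(names(object@trueResponsible), names(r)))
    msg <- c(msg, "trueResponsible must be named by the table's proteins, in order")
  else if (any(object@trueResponsible < 1L | object@trueResponsible > r))
    msg <- c(msg, "trueResponsible indices must lie in 1..r_i")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticIdrDataset", function(object) {
  cat("SyntheticIdrDataset\n")
  show(object@featureTable)
  cat("  true support size:", sum(object@trueCoefficients != 0),
      " intercept:", object@trueIntercept, "\n")
  cat("  label prevalence:",
      round(mean(annotationMatrix(object@annotations)[, 1]), 3), "\n")
})
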