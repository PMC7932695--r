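#' @include AllClasses.R
NULL

.FIT_FORMAT <- "faidr-fit/1"

## detect delimiter from the header line: tab wins, else comma
.detectSep <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (grepl("\t", hdr)) "\t" else ","
}

## parse "PROTEIN|start-end" or "PROTEIN|j" IDR identifiers; the protein id
## is everything before the last '|'
.parseIdrIds <- function(ids) {
  bar <- regexpr("\\|[^|]*$", ids)
  if (any(bar < 0))
    stop("IDR identifier lacks a '|' separator: ", ids[which(bar < 0)[1]])
  protein <- substr(ids, 1, bar - 1)
  tail <- substr(ids, bar + 1, nchar(ids))
  coord <- grepl("^[0-9]+-[0-9]+$", tail)
  ord <- grepl("^[0-9]+$", tail)
  if (any(!coord & !ord))
    stop("IDR identifier suffix is neither 'start-end' nor an ordinal: ",
         ids[which(!coord & !ord)[1]])
  start <- rep(NA_integer_, length(ids))
  end <- rep(NA_integer_, length(ids))
  idx <- rep(NA_integer_, length(ids))
  if (any(coord)) {
    parts <- strsplit(tail[coord], "-", fixed = TRUE)
    start[coord] <- as.integer(vapply(parts, `[`, "", 1L))
    end[coord] <- as.integer(vapply(parts, `[`, "", 2L))
  }
  idx[ord] <- as.integer(tail[ord])
  list(protein = protein, start = start, end = end, index = idx)
}

#' Read a per-IDR feature table
#'
#' Delimited text (tab by default, comma auto-detected) with a header row
#' of feature names; the first column holds IDR identifiers of the form
#' `"PROTEIN|start-end"` (1-based inclusive amino-acid coordinates) or
#' `"PROTEIN|j"` (ordinal, for coordinate-free data). Row order is
#' preserved and protein grouping is inferred from the identifier prefix.
#'
#' @param path Path to the file.
#' @param sep Field separator; `NULL` (default) auto-detects.
#' @return An [IdrFeatureTable-class].
#' @seealso [writeFeatureTable()]
#' @export
readFeatureTable <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- .detectSep(path)
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   colClasses = "character", na.strings = NULL)
  if (ncol(df) < 2) stop("feature table needs an id column plus features")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate IDR identifier: ", ids[duplicated(ids)][1])
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) | vals == "", arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-numeric or missing feature value at row ", bad[1, 1],
         " ('", ids[bad[1, 1]], "'), column '", colnames(vals)[bad[1, 2]], "'")
  colnames(num) <- colnames(vals)
  p <- .parseIdrIds(ids)
  idx <- p$index
  miss <- is.na(idx)
  if (any(miss))
    idx[miss] <- stats::ave(seq_along(ids), p$protein,
                            FUN = seq_along)[miss]
  IdrFeatureTable(num, proteinId = p$protein, start = p$start, end = p$end,
                  idrIndex = idx, idrId = ids)
}

#' Write a per-IDR feature table
#'
#' Tab-separated with full (15 significant digit) precision, so that a
#' read/write round trip preserves values to at least 12 significant
#' digits and row order exactly.
#'
#' @param x An [IdrFeatureTable-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(x, path) {
  stopifnot(is(x, "IdrFeatureTable"))
  m <- featureMatrix(x)
  df <- data.frame(idr_id = rownames(m),
                   format(m, digits = 15, trim = TRUE, scientific = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a protein-level binary annotation table
#'
#' Delimited text with a header of function names; the first column holds
#' protein identifiers and every cell must be 0 or 1.
#'
#' @param path Path to the file.
#' @param sep Field separator; `NULL` (default) auto-detects.
#' @return An [AnnotationTable-class].
#' @export
readAnnotationTable <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- .detectSep(path)
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   colClasses = "character", na.strings = NULL)
  if (ncol(df) < 2) stop("annotation table needs an id column plus functions")
  ids <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!all(vals %in% c("0", "1"))) {
    bad <- which(!(vals %in% c("0", "1")), arr.ind = FALSE)[1]
    rc <- arrayInd(bad, dim(vals))
    stop("annotation cell must be 0 or 1; found '", vals[bad], "' at row ",
         rc[1], " ('", ids[rc[1]], "'), column '", colnames(vals)[rc[2]], "'")
  }
  m <- matrix(as.integer(vals), nrow(vals), ncol(vals),
              dimnames = list(ids, colnames(vals)))
  AnnotationTable(m)
}

#' Write an annotation table
#'
#' @param x An [AnnotationTable-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeAnnotationTable <- function(x, path) {
  stopifnot(is(x, "AnnotationTable"))
  m <- annotationMatrix(x)
  df <- data.frame(protein_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map experimental site coordinates onto IDR-level binary labels
#'
#' An IDR is labelled 1 iff at least one site position p satisfies
#' `start <= p <= end` for that IDR (1-based, inclusive on both ends); all
#' other IDRs are labelled 0. Sites on proteins absent from the table are
#' skipped with a warning giving the count.
#'
#' @param sites data.frame with columns `protein_id` and `position`
#'   (1-based amino-acid index).
#' @param features An [IdrFeatureTable-class] whose IDRs carry coordinates.
#' @return Named integer 0/1 vector, one entry per IDR row (an IDR-level
#'   label set).
#' @export
mapSitesToIdrs <- function(sites, features) {
  stopifnot(is(features, "IdrFeatureTable"),
            all(c("protein_id", "position") %in% names(sites)))
  co <- idrCoordinates(features)
  if (all(is.na(co$start)))
    stop("feature table carries no IDR coordinates")
  labels <- setNames(integer(nrow(co)), co$idr_id)
  skipped <- 0L
  for (k in seq_len(nrow(sites))) {
    p <- sites$protein_id[k]
    pos <- sites$position[k]
    rows <- which(co$protein_id == p)
    if (!length(rows)) { skipped <- skipped + 1L; next }
    hit <- rows[!is.na(co$start[rows]) &
                  co$start[rows] <= pos & pos <= co$end[rows]]
    labels[hit] <- 1L
  }
  if (skipped > 0)
    warning(skipped, " site(s) on proteins absent from the feature table ",
            "were skipped")
  labels
}

#' Read / write IDR-level label files
#'
#' Two-column tab-separated text: `idr_id` and a 0/1 label.
#'
#' @param path File path.
#' @return `readIdrLabels`: named integer vector.
#' @export
readIdrLabels <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE)
  lab <- as.integer(df[[2]])
  if (!all(lab %in% c(0L, 1L))) stop("IDR labels must be 0/1")
  setNames(lab, as.character(df[[1]]))
}

#' @rdname readIdrLabels
#' @param labels Named 0/1 vector.
#' @export
writeIdrLabels <- function(labels, path) {
  write.table(data.frame(idr_id = names(labels), label = as.integer(labels)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize / deserialize a fitted model
#'
#' JSON-structured text carrying a format version; `readFit(writeFit(fit))`
#' reproduces every field to full precision. A file with a different (or
#' missing) format version, or a truncated file, raises an error.
#'
#' @param fit A [FaidrFit-class].
#' @param path File path.
#' @return `writeFit`: `path`, invisibly. `readFit`: a [FaidrFit-class].
#' @export
writeFit <- function(fit, path) {
  stopifnot(is(fit, "FaidrFit"))
  obj <- list(
    format = .FIT_FORMAT,
    function_name = fit@functionName,
    coefficients = as.list(setNames(fit@coefficients,
                                    names(fit@coefficients))),
    intercept = fit@intercept,
    responsibilities = as.list(setNames(fit@responsibilities,
                                        names(fit@responsibilities))),
    protein_id = fit@proteinId,
    lambda = fit@lambda,
    alpha = fit@alpha,
    n_em_iterations = fit@nEmIterations,
    converged = fit@converged,
    objective_trace = fit@objectiveTrace,
    control = fit@control
  )
  # I(17) significant digits: doubles survive the text round trip exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeFit
#' @export
readFit <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("cannot parse fit file (truncated or corrupt): ",
                         conditionMessage(e)))
  if (is.null(obj$format) || !identical(obj$format, .FIT_FORMAT))
    stop("fit file format version mismatch: expected '", .FIT_FORMAT,
         "', found '", if (is.null(obj$format)) "<none>" else obj$format, "'")
  ctl <- obj$control
  s <- suppressWarnings(as.integer(ctl$seed))  # NA seeds serialize as "NA"
  ctl$seed <- if (length(s) != 1 || is.na(s)) NA_integer_ else s
  cf <- unlist(obj$coefficients)
  storage.mode(cf) <- "double"
  rs <- unlist(obj$responsibilities)
  storage.mode(rs) <- "double"
  new("FaidrFit",
      functionName = obj$function_name,
      coefficients = cf,
      intercept = as.numeric(obj$intercept),
      responsibilities = rs,
      proteinId = as.character(obj$protein_id),
      lambda = obj$lambda,
      alpha = obj$alpha,
      nEmIterations = as.integer(obj$n_em_iterations),
      converged = obj$converged,
      objectiveTrace = as.numeric(obj$objective_trace),
      control = ctl)
}
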