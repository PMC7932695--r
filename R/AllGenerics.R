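#' @include faidr-package.R
NULL

#' Accessor generics
#'
#' Accessors for the core data containers: the per-IDR feature matrix, the
#' feature names, the protein identifiers, the per-protein IDR counts
#' (\eqn{r_i}) and the IDR identifiers.
#'
#' @param x An object (e.g. [IdrFeatureTable-class], [AnnotationTable-class],
#'   [FaidrFit-class]).
#' @param ... Additional arguments passed to methods.
#' @return See the individual methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x, ...) standardGeneric("featureMatrix"))

#' @rdname accessors
#' @export
setGeneric("featureNames", function(x, ...) standardGeneric("featureNames"))

#' @rdname accessors
#' @export
setGeneric("proteinIds", function(x, ...) standardGeneric("proteinIds"))

#' @rdname accessors
#' @export
setGeneric("idrIds", function(x, ...) standardGeneric("idrIds"))

#' @rdname accessors
#' @export
setGeneric("idrCounts", function(x, ...) standardGeneric("idrCounts"))

#' @rdname accessors
#' @export
setGeneric("idrProtein", function(x, ...) standardGeneric("idrProtein"))

#' @rdname accessors
#' @export
setGeneric("idrCoordinates", function(x, ...) standardGeneric("idrCoordinates"))

#' @rdname accessors
#' @export
setGeneric("functionNames", function(x, ...) standardGeneric("functionNames"))

#' @rdname accessors
#' @export
setGeneric("annotationMatrix", function(x, ...) standardGeneric("annotationMatrix"))

#' Fit accessor generics
#'
#' Accessors for fitted model objects: the sparse coefficient vector, the
#' intercept, and the per-IDR responsibilities \eqn{\langle X_{ij}\rangle}
#' (posterior probability that IDR \eqn{j} of protein \eqn{i} carries the
#' function).
#'
#' @param object A [FaidrFit-class].
#' @param ... Additional arguments passed to methods.
#' @return Numeric vector (named by feature or IDR id) or scalar.
#' @name fit-accessors
NULL

#' @rdname fit-accessors
#' @export
setGeneric("responsibilities", function(object, ...) standardGeneric("responsibilities"))

#' @rdname fit-accessors
#' @export
setGeneric("intercept", function(object, ...) standardGeneric("intercept"))

#' Prediction generics
#'
#' `predictIdr` scores every IDR row independently with the fitted logistic
#' model; `predictProtein` averages those scores uniformly over the
#' \eqn{r_i} IDRs of each protein (the uninformative-prior mixture used for
#' unseen proteins).
#'
#' @param object A [FaidrFit-class].
#' @param features An [IdrFeatureTable-class] whose feature names match the fit.
#' @param ... Additional arguments passed to methods.
#' @return Named numeric vector of probabilities in (0, 1): one per IDR for
#'   `predictIdr`, one per protein for `predictProtein`.
#' @name predict-generics
NULL

#' @rdname predict-generics
#' @export
setGeneric("predictIdr", function(object, features, ...) standardGeneric("predictIdr"))

#' @rdname predict-generics
#' @export
setGeneric("predictProtein", function(object, features, ...) standardGeneric("predictProtein"))
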