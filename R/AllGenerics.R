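#' Accessors for TraitTable and model objects
#'
#' @param x a [TraitTable-class], [KMeansResult-class] or other package
#'   object, as documented per method.
#' @name accessors
NULL

#' @rdname accessors
#' @return `traitValues`: the underlying data.frame of cell values.
#' @export
setGeneric("traitValues", function(x) standardGeneric("traitValues"))

#' @rdname accessors
#' @return `observedMask`: logical matrix, `TRUE` for observed cells.
#' @export
setGeneric("observedMask", function(x) standardGeneric("observedMask"))

#' @rdname accessors
#' @return `columnKinds`: named character vector of column kinds.
#' @export
setGeneric("columnKinds", function(x) standardGeneric("columnKinds"))

#' @rdname accessors
#' @return `scaleTags`: named character vector of continuous-column scales.
#' @export
setGeneric("scaleTags", function(x) standardGeneric("scaleTags"))

#' @rdname accessors
#' @return `centroids`: k x d matrix of cluster centroids.
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' @rdname accessors
#' @return `assignments`: integer cluster assignments.
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))

#' @rdname accessors
#' @return `inertia`: within-cluster sum of squares.
#' @export
setGeneric("inertia", function(x) standardGeneric("inertia"))

#' @rdname accessors
#' @return `incumbent`: best configuration found by a search.
#' @export
setGeneric("incumbent", function(x) standardGeneric("incumbent"))

#' @rdname accessors
#' @return `searchTrace`: evaluation trace of a search.
#' @export
setGeneric("searchTrace", function(x) standardGeneric("searchTrace"))

#' @rdname accessors
#' @return `metricsTable`: one-row data.frame of the seven metrics.
#' @export
setGeneric("metricsTable", function(x) standardGeneric("metricsTable"))
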