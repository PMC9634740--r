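#' Accessors for netpharm classes
#'
#' @param x a netpharm object.
#' @param ... further arguments passed to methods.
#' @return `genes()` the character vector of symbols; `setName()` the set
#'   label; `survivors()` node ids surviving a screen round; `thresholds()`
#'   the named medians applied in a round; `nRounds()` the number of
#'   completed rounds.
#' @name netpharm-accessors
NULL

#' @rdname netpharm-accessors
#' @export
setGeneric("genes", function(x, ...) standardGeneric("genes"))

#' @rdname netpharm-accessors
#' @export
setGeneric("setName", function(x, ...) standardGeneric("setName"))

#' @rdname netpharm-accessors
#' @export
setGeneric("survivors", function(x, ...) standardGeneric("survivors"))

#' @rdname netpharm-accessors
#' @export
setGeneric("thresholds", function(x, ...) standardGeneric("thresholds"))

#' @rdname netpharm-accessors
#' @export
setGeneric("nRounds", function(x) standardGeneric("nRounds"))

#' Write a pipeline product to disk
#'
#' Tables are written as CSV, graphs as canonical two-column TSV edge lists,
#' and list-like run summaries as JSON. Output is bit-stable for identical
#' inputs.
#'
#' @param obj a data.frame, igraph, [GeneSet-class] or list.
#' @param path output file path.
#' @param ... further arguments passed to methods.
#' @return `path`, invisibly.
#' @export
setGeneric("writeResults", function(obj, path, ...) standardGeneric("writeResults"))
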