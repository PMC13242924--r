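#' @name h5adkit-accessors
#' @title Accessors for AnnData containers
#'
#' @description
#' Generic accessors shared by in-memory ([AnnData()]) and file-backed
#' ([readH5AD()] with `mode = "backed"`) containers. The container follows
#' the AnnData convention: observations (cells) are rows, variables
#' (features/genes) are columns.
#'
#' @param x An `AnnData` or `H5ADBacked` object.
#' @param value Replacement value.
#' @return The slot value, or (for setters) the modified container.
NULL

#' @rdname h5adkit-accessors
#' @export
setGeneric("adX", function(x) standardGeneric("adX"))
#' @rdname h5adkit-accessors
#' @export
setGeneric("adX<-", function(x, value) standardGeneric("adX<-"))
#' @rdname h5adkit-accessors
#' @export
setGeneric("adLayers", function(x) standardGeneric("adLayers"))
#' @rdname h5adkit-accessors
#' @export
setGeneric("adLayers<-", function(x, value) standardGeneric("adLayers<-"))
#' @rdname h5adkit-accessors
#' @export
setGeneric("adObs", function(x) standardGeneric("adObs"))
#' @rdname h5adkit-accessors
#' @export
setGeneric("adObs<-", function(x, value) standardGeneric("adObs<-"))
#' @rdname h5adkit-accessors
#' @export
setGeneric("adVar", function(x) standardGeneric("adVar"))
#' @rdname h5adkit-accessors
#' @export
setGeneric("adVar<-", function(x, value) standardGeneric("adVar<-"))
#' @rdname h5adkit-accessors
#' @export
setGeneric("adObsm", function(x) standardGeneric("adObsm"))
#' @rdname h5adkit-accessors
#' @export
setGeneric("adObsm<-", function(x, value) standardGeneric("adObsm<-"))
#' @rdname h5adkit-accessors
#' @export
setGeneric("adVarm", function(x) standardGeneric("adVarm"))
#' @rdname h5adkit-accessors
#' @export
setGeneric("adVarm<-", function(x, value) standardGeneric("adVarm<-"))
#' @rdname h5adkit-accessors
#' @export
setGeneric("adObsp", function(x) standardGeneric("adObsp"))
#' @rdname h5adkit-accessors
#' @export
setGeneric("adObsp<-", function(x, value) standardGeneric("adObsp<-"))
#' @rdname h5adkit-accessors
#' @export
setGeneric("adVarp", function(x) standardGeneric("adVarp"))
#' @rdname h5adkit-accessors
#' @export
setGeneric("adVarp<-", function(x, value) standardGeneric("adVarp<-"))
#' @rdname h5adkit-accessors
#' @export
setGeneric("adUns", function(x) standardGeneric("adUns"))
#' @rdname h5adkit-accessors
#' @export
setGeneric("adUns<-", function(x, value) standardGeneric("adUns<-"))
#' @rdname h5adkit-accessors
#' @export
setGeneric("adRaw", function(x) standardGeneric("adRaw"))
#' @rdname h5adkit-accessors
#' @export
setGeneric("adRaw<-", function(x, value) standardGeneric("adRaw<-"))
#' @rdname h5adkit-accessors
#' @export
setGeneric("obsNames", function(x) standardGeneric("obsNames"))
#' @rdname h5adkit-accessors
#' @export
setGeneric("obsNames<-", function(x, value) standardGeneric("obsNames<-"))
#' @rdname h5adkit-accessors
#' @export
setGeneric("varNames", function(x) standardGeneric("varNames"))
#' @rdname h5adkit-accessors
#' @export
setGeneric("varNames<-", function(x, value) standardGeneric("varNames<-"))
#' @rdname h5adkit-accessors
#' @export
setGeneric("nObs", function(x) standardGeneric("nObs"))
#' @rdname h5adkit-accessors
#' @export
setGeneric("nVar", function(x) standardGeneric("nVar"))

#' Materialize a file-backed container in memory
#'
#' @param x An `H5ADBacked` handle (no-op for in-memory containers).
#' @param ... Further arguments for methods.
#' @return An [AnnData()] container with every slot decoded.
#' @export
setGeneric("toMemory", function(x, ...) standardGeneric("toMemory"))

#' Loss report of a conversion
#'
#' Conversions between object layouts ([toSCE()], [toSeurat()] and inverses)
#' attach a report of slots that were dropped, stashed under a reserved key,
#' or renamed. `lossReport()` retrieves it.
#'
#' @param x An object returned by one of the converters.
#' @return A `LossReport` object, or `NULL` when none is attached.
#' @export
setGeneric("lossReport", function(x) standardGeneric("lossReport"))
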