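#' File-backed AnnData handles
#'
#' `readH5AD(path, mode = "backed")` returns an `H5ADBacked` handle:
#' metadata slots (`obs`, `var`, `uns`, axis names, the slot inventory) are
#' decoded eagerly at open time, while matrix-bearing slots (`X`, `layers`,
#' `obsm`, `varm`, `obsp`, `varp`, `raw$X`) stay on disk until an accessor
#' or [toMemory()] materializes them. Backed handles are read-only; saving
#' always targets a new file via [writeH5AD()] after [toMemory()].
#'
#' Materialized slots are cached on the handle, so repeated access reads
#' the file once. The handle re-opens the backing file per access; if the
#' file has been deleted or moved, accessors fail citing the path.
#'
#' @name H5ADBacked
#' @aliases H5ADBacked-class
NULL

setClass("H5ADBacked", representation(path = "character",
                                      .data = "environment"))

.open_backed <- function(path, legacy = "infer") {
  h5 <- .h5_open_ro(path)
  on.exit(.h5_close(h5))
  kids <- .h5_children(h5, "/")
  if (!all(c("obs", "var") %in% kids)) {
    stop("not an AnnData file (missing obs/var at the root): ", path,
         call. = FALSE)
  }
  e <- new.env(parent = emptyenv())
  e$legacy <- legacy
  e$obs <- readElement(h5, "obs", legacy)
  e$var <- readElement(h5, "var", legacy)
  e$obsNames <- attr(e$obs, "h5ad_index")
  e$varNames <- attr(e$var, "h5ad_index")
  e$n_obs <- length(e$obsNames)
  e$n_var <- length(e$varNames)
  e$uns <- if ("uns" %in% kids) readElement(h5, "uns", legacy) else list()
  e$has_X <- "X" %in% kids
  e$has_raw <- "raw" %in% kids
  inventory <- list()
  for (sl in c("layers", "obsm", "varm", "obsp", "varp")) {
    inventory[[sl]] <- if (sl %in% kids) .h5_children(h5, sl) else character(0)
  }
  if (e$has_raw) {
    rkids <- .h5_children(h5, "raw")
    e$raw_var <- if ("var" %in% rkids) readElement(h5, "raw/var", legacy)
    inventory$raw_varm <- if ("varm" %in% rkids) {
      .h5_children(h5, "raw/varm")
    } else {
      character(0)
    }
  }
  e$inventory <- inventory
  e$cache <- new.env(parent = emptyenv())
  new("H5ADBacked", path = path, .data = e)
}

.backed_read <- function(x, path) {
  e <- x@.data
  key <- path
  if (!is.null(e$cache[[key]])) return(e$cache[[key]])
  if (!file.exists(x@path)) {
    stop("backing file no longer exists: '", x@path, "'", call. = FALSE)
  }
  h5 <- .h5_open_ro(x@path)
  on.exit(.h5_close(h5))
  val <- readElement(h5, path, e$legacy)
  e$cache[[key]] <- val
  val
}

.backed_mapping <- function(x, slot, prefix = slot) {
  keys <- x@.data$inventory[[slot]]
  out <- lapply(keys, function(k) .backed_read(x, paste0(prefix, "/", k)))
  if (length(out) > 0L) names(out) <- keys
  out
}

#' @rdname h5adkit-accessors
setMethod("adX", "H5ADBacked", function(x) {
  if (!x@.data$has_X) return(NULL)
  .backed_read(x, "X")
})
#' @rdname h5adkit-accessors
setMethod("adLayers", "H5ADBacked", function(x) .backed_mapping(x, "layers"))
#' @rdname h5adkit-accessors
setMethod("adObs", "H5ADBacked", function(x) x@.data$obs)
#' @rdname h5adkit-accessors
setMethod("adVar", "H5ADBacked", function(x) x@.data$var)
#' @rdname h5adkit-accessors
setMethod("adObsm", "H5ADBacked", function(x) .backed_mapping(x, "obsm"))
#' @rdname h5adkit-accessors
setMethod("adVarm", "H5ADBacked", function(x) .backed_mapping(x, "varm"))
#' @rdname h5adkit-accessors
setMethod("adObsp", "H5ADBacked", function(x) .backed_mapping(x, "obsp"))
#' @rdname h5adkit-accessors
setMethod("adVarp", "H5ADBacked", function(x) .backed_mapping(x, "varp"))
#' @rdname h5adkit-accessors
setMethod("adUns", "H5ADBacked", function(x) x@.data$uns)
#' @rdname h5adkit-accessors
setMethod("adRaw", "H5ADBacked", function(x) {
  e <- x@.data
  if (!e$has_raw) return(NULL)
  raw <- list(X = .backed_read(x, "raw/X"))
  if (!is.null(e$raw_var)) {
    raw$var <- e$raw_var
    raw$varNames <- attr(e$raw_var, "h5ad_index")
  }
  varm <- .backed_mapping(x, "raw_varm", prefix = "raw/varm")
  if (length(varm) > 0L) raw$varm <- varm
  raw
})
#' @rdname h5adkit-accessors
setMethod("obsNames", "H5ADBacked", function(x) x@.data$obsNames)
#' @rdname h5adkit-accessors
setMethod("varNames", "H5ADBacked", function(x) x@.data$varNames)
#' @rdname h5adkit-accessors
setMethod("nObs", "H5ADBacked", function(x) x@.data$n_obs)
#' @rdname h5adkit-accessors
setMethod("nVar", "H5ADBacked", function(x) x@.data$n_var)

#' @export
setMethod("dim", "H5ADBacked", function(x) c(x@.data$n_obs, x@.data$n_var))

#' @export
setMethod("show", "H5ADBacked", function(object) {
  e <- object@.data
  cat(sprintf("H5ADBacked (read-only) %d x %d <%s>\n",
              e$n_obs, e$n_var, object@path))
  inv <- e$inventory
  for (sl in c("layers", "obsm", "varm", "obsp", "varp")) {
    if (length(inv[[sl]]) > 0L) {
      cat(sprintf("    %s: %s\n", sl, paste(inv[[sl]], collapse = ", ")))
    }
  }
  cat(sprintf("    X: %s  raw: %s\n",
              if (e$has_X) "on disk" else "<absent>",
              if (e$has_raw) "on disk" else "<absent>"))
  invisible(NULL)
})

#' @rdname toMemory
setMethod("toMemory", "H5ADBacked", function(x, ...) {
  e <- x@.data
  AnnData(
    X = adX(x),
    layers = adLayers(x),
    obs = e$obs,
    var = e$var,
    obsNames = e$obsNames,
    varNames = e$varNames,
    obsm = adObsm(x),
    varm = adVarm(x),
    obsp = adObsp(x),
    varp = adVarp(x),
    uns = e$uns,
    raw = adRaw(x)
  )
})

#' @rdname toMemory
setMethod("toMemory", "AnnData", function(x, ...) x)
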