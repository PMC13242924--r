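#' @importFrom methods new is as setClass setGeneric setMethod setValidity validObject show
NULL

# Element encodings written by this package, at the versions emitted by the
# current reference implementation of the AnnData on-disk format.
.ENCODINGS <- c(
  "array"            = "0.2.0",
  "string-array"     = "0.2.0",
  "string"           = "0.2.0",
  "numeric-scalar"   = "0.2.0",
  "csr_matrix"       = "0.1.0",
  "csc_matrix"       = "0.1.0",
  "dataframe"        = "0.2.0",
  "categorical"      = "0.2.0",
  "nullable-integer" = "0.1.0",
  "nullable-boolean" = "0.1.0",
  "dict"             = "0.1.0",
  "raw"              = "0.1.0",
  "anndata"          = "0.1.0"
)

#' Registry of supported on-disk element encodings
#'
#' @return Named character vector mapping each supported `encoding-type`
#'   token to the `encoding-version` this package writes.
#' @export
#' @examples
#' encodingRegistry()
encodingRegistry <- function() .ENCODINGS

# structured, path-addressed codec errors
.h5ad_stop <- function(path, msg, class = "h5adkit_codec_error") {
  stop(structure(
    class = c(class, "h5adkit_error", "error", "condition"),
    list(message = sprintf("[%s] %s", path, msg), call = NULL)
  ))
}

.version_ok <- function(v) {
  is.character(v) && length(v) == 1L && grepl("^[0-9]+(\\.[0-9]+)*$", v)
}

#' Detect the encoding of an element inside an H5AD file
#'
#' Reads the `encoding-type` and `encoding-version` attributes of the HDF5
#' object at `path`. When the attributes are absent (legacy files predating
#' the on-disk specification's attribute scheme), behaviour is governed by
#' `legacy`: `"infer"` (default) guesses the encoding from the object's
#' structure and warns, `"error"` fails.
#'
#' @param file Path to an H5AD/HDF5 file, or an open rhdf5 file handle.
#' @param path Slash-separated element path inside the file.
#' @param legacy Policy for elements without encoding attributes.
#' @return A list with elements `type`, `version` and `path`.
#' @export
detectEncoding <- function(file, path, legacy = c("infer", "error")) {
  legacy <- match.arg(legacy)
  if (is.character(file)) {
    h5 <- .h5_open_ro(file)
    on.exit(.h5_close(h5))
  } else {
    h5 <- file
  }
  if (!.h5_exists(h5, path)) {
    .h5ad_stop(path, "no such element in file")
  }
  at <- .h5_read_attrs(h5, path)
  type <- at[["encoding-type"]]
  version <- at[["encoding-version"]]
  if (is.null(type)) {
    if (legacy == "error") {
      .h5ad_stop(path, "element has no encoding-type attribute",
                 "h5adkit_legacy_error")
    }
    desc <- .infer_encoding(h5, path)
    warning("element '", path, "' has no encoding attributes; inferred '",
            desc$type, "' from its structure", call. = FALSE)
    return(desc)
  }
  if (!type %in% names(.ENCODINGS)) {
    .h5ad_stop(path, sprintf("unknown encoding-type '%s'", type),
               "h5adkit_unknown_encoding")
  }
  if (!is.null(version) && !.version_ok(version)) {
    .h5ad_stop(path, sprintf("malformed encoding-version '%s'", version))
  }
  list(type = type, version = version, path = path)
}

# Structure-based inference for files lacking encoding attributes.
.infer_encoding <- function(h5, path) {
  mk <- function(type) list(type = type, version = NULL, path = path)
  if (.h5_is_group(h5, path)) {
    kids <- .h5_children(h5, path)
    at <- .h5_read_attrs(h5, path)
    if (all(c("data", "indices", "indptr") %in% kids)) {
      shape <- at[["shape"]]
      if (is.null(shape)) {
        .h5ad_stop(path, "sparse-like group without a shape attribute")
      }
      nip <- .h5_dims(h5, paste0(path, "/indptr"))
      if (length(nip) == 1L && nip == shape[1] + 1L) return(mk("csr_matrix"))
      return(mk("csc_matrix"))
    }
    if (all(c("categories", "codes") %in% kids)) return(mk("categorical"))
    if (all(c("values", "mask") %in% kids)) {
      cls <- .h5_dclass(h5, paste0(path, "/values"))
      if (cls == "ENUM") return(mk("nullable-boolean"))
      return(mk("nullable-integer"))
    }
    if (!is.null(at[["_index"]])) return(mk("dataframe"))
    return(mk("dict"))
  }
  dclass <- .h5_dclass(h5, path)
  rank <- length(.h5_dims(h5, path))
  if (dclass == "STRING") {
    if (rank == 0L) return(mk("string"))
    return(mk("string-array"))
  }
  if (rank == 0L) return(mk("numeric-scalar"))
  mk("array")
}

# stamp encoding attributes on a freshly written element
.write_encoding_attrs <- function(h5, path, type) {
  .h5_write_attr(h5, path, "encoding-type", type)
  .h5_write_attr(h5, path, "encoding-version", unname(.ENCODINGS[[type]]))
  invisible(NULL)
}
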