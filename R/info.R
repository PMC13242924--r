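#' Summarize the contents of an H5AD file
#'
#' Lists every root slot and its children with their declared encodings
#' and shapes, without decoding matrix payloads.
#'
#' @param path Path to an H5AD file.
#' @return A data.frame with columns `path`, `encoding`, `shape`
#'   (invisible when printed via the CLI).
#' @export
h5adInfo <- function(path) {
  h5 <- .h5_open_ro(path)
  on.exit(.h5_close(h5))
  rows <- list()
  describe <- function(p) {
    desc <- tryCatch(
      suppressWarnings(detectEncoding(h5, p, legacy = "infer")),
      error = function(e) list(type = "?", version = NULL))
    shape <- if (desc$type %in% c("csr_matrix", "csc_matrix")) {
      paste(.h5_read_attrs(h5, p)[["shape"]], collapse = " x ")
    } else if (desc$type %in% c("dict", "raw", "dataframe")) {
      if (desc$type == "dataframe") {
        at <- .h5_read_attrs(h5, p)
        n <- tryCatch(.h5_dims(h5, paste0(p, "/", at[["_index"]]))[1],
                      error = function(e) NA_integer_)
        ncol <- length(at[["column-order"]])
        paste0(n, " x ", ncol)
      } else {
        paste0(length(.h5_children(h5, p)), " element(s)")
      }
    } else if (!.h5_is_group(h5, p)) {
      d <- .h5_dims(h5, p)
      if (length(d) == 0L) "scalar" else paste(d, collapse = " x ")
    } else {
      ""
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      path = paste0("/", p), encoding = desc$type, shape = shape,
      stringsAsFactors = FALSE)
    if (desc$type %in% c("dict", "raw")) {
      for (k in .h5_children(h5, p)) describe(paste0(p, "/", k))
    }
  }
  for (k in .h5_children(h5, "/")) describe(k)
  do.call(rbind, rows)
}
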