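#' Semantic diff between two H5AD files
#'
#' Compares *decoded* content, not bytes: two files are equal when every
#' element path decodes to the same logical value, regardless of how the
#' writing HDF5 binding laid the bytes out (integer widths, fixed- versus
#' variable-length strings, compression, chunking). Dataframes are
#' compared column by column, mappings key by key, so each discrepancy is
#' localized to its exact slash-separated path.
#'
#' Kinds of entries: `missing_left`/`missing_right` (element present in
#' only one file), `type_mismatch` (incompatible decoded types, or
#' different declared encodings under `strictEncoding`), `shape_mismatch`,
#' `value_mismatch` (numeric comparison honours `tol`), `attr_mismatch`
#' (semantic attributes such as a categorical's ordered flag, a
#' dataframe's column order or index name).
#'
#' @param pathA,pathB Files to compare.
#' @param tol Absolute tolerance for numeric values. Default 0 (exact).
#' @param strictEncoding When `TRUE`, the same logical matrix stored dense
#'   in one file and sparse in the other (or CSR vs CSC) is reported as a
#'   `type_mismatch`; when `FALSE` (default) only decoded values matter.
#' @return A `DiffReport`; `isEqual(report)` is `TRUE` iff no entries.
#' @aliases DiffReport-class
#' @export
diffH5AD <- function(pathA, pathB, tol = 0, strictEncoding = FALSE) {
  ta <- .leaf_tree(pathA)
  tb <- .leaf_tree(pathB)
  entries <- list()
  add <- function(path, kind, detail) {
    entries[[length(entries) + 1L]] <<- data.frame(
      path = path, kind = kind, detail = detail, stringsAsFactors = FALSE)
  }
  paths <- sort(union(names(ta), names(tb)))
  for (p in paths) {
    a <- ta[[p]]
    b <- tb[[p]]
    if (is.null(a)) {
      add(p, "missing_left", "element only in second file")
      next
    }
    if (is.null(b)) {
      add(p, "missing_right", "element only in first file")
      next
    }
    .compare_leaf(a, b, p, tol, strictEncoding, add)
  }
  df <- if (length(entries) == 0L) {
    data.frame(path = character(0), kind = character(0),
               detail = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, entries)
  }
  new("DiffReport", pathA = pathA, pathB = pathB, entries = df)
}

setClass("DiffReport",
         representation(pathA = "character", pathB = "character",
                        entries = "data.frame"))

#' @rdname diffH5AD
#' @param report A `DiffReport`.
#' @export
isEqual <- function(report) nrow(report@entries) == 0L

#' @rdname diffH5AD
#' @export
diffEntries <- function(report) report@entries

#' @export
setMethod("show", "DiffReport", function(object) {
  if (isEqual(object)) {
    cat("DiffReport: files are semantically equal\n")
  } else {
    cat("DiffReport:", nrow(object@entries), "difference(s)\n")
    df <- object@entries
    for (k in seq_len(nrow(df))) {
      cat(sprintf("  %-14s %s (%s)\n", df$kind[k], df$path[k], df$detail[k]))
    }
  }
  invisible(NULL)
})

# ---- leaf tree -------------------------------------------------------------

# Flatten a file into comparable leaves keyed by /slash/path. Sparse
# matrices, arrays, scalars and categoricals are one leaf each; dataframes
# contribute one leaf per column plus an index leaf; dicts recurse.
.leaf_tree <- function(path) {
  h5 <- .h5_open_ro(path)
  on.exit(.h5_close(h5))
  leaves <- new.env(parent = emptyenv())
  for (k in .h5_children(h5, "/")) {
    .collect_leaves(h5, k, paste0("/", k), leaves)
  }
  as.list(leaves)
}

.collect_leaves <- function(h5, path, label, leaves) {
  desc <- tryCatch(
    suppressWarnings(detectEncoding(h5, path, legacy = "infer")),
    error = function(e) NULL)
  if (is.null(desc)) {
    leaves[[label]] <- list(enc = "unreadable", value = NULL)
    return(invisible(NULL))
  }
  if (desc$type %in% c("dict", "raw")) {
    for (k in .h5_children(h5, path)) {
      .collect_leaves(h5, paste0(path, "/", k), paste0(label, "/", k), leaves)
    }
    return(invisible(NULL))
  }
  if (desc$type == "dataframe") {
    at <- .h5_read_attrs(h5, path)
    index_name <- at[["_index"]]
    col_order <- as.character(at[["column-order"]] %||% character(0))
    leaves[[paste0(label, "/.index")]] <- list(
      enc = "string-array", index_name = index_name,
      value = tryCatch(.h5_read_dataset(h5, paste0(path, "/", index_name)),
                       error = function(e) NULL))
    leaves[[paste0(label, "/.column-order")]] <- list(
      enc = "column-order", value = col_order)
    for (cn in col_order) {
      .collect_leaves(h5, paste0(path, "/", cn), paste0(label, "/", cn),
                      leaves)
    }
    return(invisible(NULL))
  }
  val <- tryCatch(
    suppressWarnings(readElement(h5, path, legacy = "infer")),
    error = function(e) NULL)
  leaves[[label]] <- list(enc = desc$type, value = val)
  invisible(NULL)
}

# ---- leaf comparison -------------------------------------------------------

.type_category <- function(x) {
  if (is(x, "sparseMatrix") || (is.numeric(x) && !is.null(dim(x)))) {
    return("numeric-matrix")
  }
  if (is.factor(x)) return("categorical")
  if (is.character(x)) return("character")
  if (is.logical(x)) return("logical")
  if (is.numeric(x)) return("numeric")
  class(x)[1]
}

.compare_leaf <- function(a, b, path, tol, strict, add) {
  if (identical(a$enc, "column-order")) {
    if (!identical(a$value, b$value)) {
      add(path, "attr_mismatch",
          paste0("column-order differs: [",
                 paste(a$value, collapse = ","), "] vs [",
                 paste(b$value, collapse = ","), "]"))
    }
    return(invisible(NULL))
  }
  if (!is.null(a$index_name) || !is.null(b$index_name)) {
    if (!identical(a$index_name, b$index_name)) {
      add(path, "attr_mismatch", "index column name differs")
    }
  }
  if (is.null(a$value) || is.null(b$value)) {
    if (!(is.null(a$value) && is.null(b$value))) {
      add(path, "type_mismatch", "element unreadable in one file")
    }
    return(invisible(NULL))
  }
  if (strict && !identical(a$enc, b$enc)) {
    add(path, "type_mismatch",
        paste0("encodings differ: ", a$enc, " vs ", b$enc))
    return(invisible(NULL))
  }
  va <- a$value
  vb <- b$value
  ca <- .type_category(va)
  cb <- .type_category(vb)
  if (ca != cb) {
    add(path, "type_mismatch", paste0(ca, " vs ", cb))
    return(invisible(NULL))
  }
  switch(ca,
    "numeric-matrix" = {
      if (!identical(dim(va), dim(vb))) {
        add(path, "shape_mismatch",
            paste0(paste(dim(va), collapse = "x"), " vs ",
                   paste(dim(vb), collapse = "x")))
        return(invisible(NULL))
      }
      da <- as.matrix(va)
      db <- as.matrix(vb)
      if (!.num_equal(da, db, tol)) {
        add(path, "value_mismatch", .first_num_diff(da, db, tol))
      }
    },
    "categorical" = {
      if (!identical(levels(va), levels(vb))) {
        add(path, "value_mismatch", "category sets differ")
      } else if (!identical(is.ordered(va), is.ordered(vb))) {
        add(path, "attr_mismatch", "ordered flag differs")
      } else if (!identical(as.integer(va), as.integer(vb))) {
        add(path, "value_mismatch", "categorical codes differ")
      }
    },
    "numeric" = {
      if (length(va) != length(vb)) {
        add(path, "shape_mismatch",
            paste0("length ", length(va), " vs ", length(vb)))
      } else if (!.num_equal(va, vb, tol)) {
        add(path, "value_mismatch", .first_num_diff(va, vb, tol))
      }
    },
    {
      if (length(va) != length(vb)) {
        add(path, "shape_mismatch",
            paste0("length ", length(va), " vs ", length(vb)))
      } else if (!identical(unname(va), unname(vb))) {
        add(path, "value_mismatch", "values differ")
      }
    }
  )
  invisible(NULL)
}

.num_equal <- function(a, b, tol) {
  a <- as.vector(a)
  b <- as.vector(b)
  if (!identical(is.na(a), is.na(b))) return(FALSE)
  ok <- is.na(a) | (abs(as.numeric(a) - as.numeric(b)) <= tol)
  all(ok)
}

.first_num_diff <- function(a, b, tol) {
  a <- as.vector(a)
  b <- as.vector(b)
  bad <- which(xor(is.na(a), is.na(b)) |
                 (!is.na(a) & !is.na(b) &
                    abs(as.numeric(a) - as.numeric(b)) > tol))
  if (length(bad) == 0L) return("values differ")
  i <- bad[1]
  sprintf("first difference at flat index %d: %s vs %s", i,
          format(a[i]), format(b[i]))
}
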