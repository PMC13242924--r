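#' On-disk conformance validation
#'
#' [validateH5AD()] checks a file against the AnnData on-disk rules
#' without mutating it: root layout (obs/var present, children
#' recognized), encoding attributes (known `encoding-type`, parseable
#' `encoding-version`), and every structural invariant of the per-element
#' encodings (sparse triple consistency, categorical code ranges,
#' dataframe column lengths and order, nullable value/mask pairing).
#' Violations carry the element path and a stable rule id.
#'
#' @param path Path to the file to check.
#' @return A `ValidationReport`; `isConformant(report)` is `TRUE` iff the
#'   violation list is empty. An unreadable file raises an error rather
#'   than returning violations.
#' @aliases ValidationReport-class
#' @export
validateH5AD <- function(path) {
  h5 <- .h5_open_ro(path)   # unreadable file -> error, not a violation
  on.exit(.h5_close(h5))
  v <- .new_violations()
  kids <- .h5_children(h5, "/")
  for (req in c("obs", "var")) {
    if (!req %in% kids) {
      v$add("/", "root/layout", paste0("required root group '", req,
                                       "' is missing"))
    }
  }
  for (extra in setdiff(kids, .ROOT_SLOTS)) {
    v$add(paste0("/", extra), "root/unknown-child",
          "unrecognized element at the file root")
  }
  for (slot in intersect(kids, .ROOT_SLOTS)) {
    .validate_element(h5, slot, v)
  }
  new("ValidationReport", path = path, violations = v$df())
}

setClass("ValidationReport",
         representation(path = "character", violations = "data.frame"))

#' @rdname validateH5AD
#' @param report A `ValidationReport`.
#' @export
isConformant <- function(report) nrow(report@violations) == 0L

#' @rdname validateH5AD
#' @export
violations <- function(report) report@violations

#' @export
setMethod("show", "ValidationReport", function(object) {
  if (isConformant(object)) {
    cat("ValidationReport: conformant <", object@path, ">\n")
  } else {
    cat("ValidationReport:", nrow(object@violations), "violation(s) <",
        object@path, ">\n")
    df <- object@violations
    for (k in seq_len(nrow(df))) {
      cat(sprintf("  [%s] %s: %s\n", df$rule[k], df$path[k], df$message[k]))
    }
  }
  invisible(NULL)
})

.new_violations <- function() {
  rows <- list()
  list(
    add = function(path, rule, message) {
      rows[[length(rows) + 1L]] <<- data.frame(
        path = path, rule = rule, message = message,
        stringsAsFactors = FALSE)
    },
    df = function() {
      if (length(rows) == 0L) {
        data.frame(path = character(0), rule = character(0),
                   message = character(0), stringsAsFactors = FALSE)
      } else {
        do.call(rbind, rows)
      }
    }
  )
}

.validate_element <- function(h5, path, v) {
  at <- tryCatch(.h5_read_attrs(h5, path), error = function(e) NULL)
  if (is.null(at)) {
    v$add(path, "enc/unreadable", "could not read attributes")
    return(invisible(NULL))
  }
  type <- at[["encoding-type"]]
  version <- at[["encoding-version"]]
  if (is.null(type)) {
    v$add(path, "enc/missing-attrs", "element has no encoding-type attribute")
    type <- tryCatch(.infer_encoding(h5, path)$type, error = function(e) NULL)
    if (is.null(type)) return(invisible(NULL))
  } else if (!type %in% names(.ENCODINGS)) {
    v$add(path, "enc/unknown-type",
          paste0("unknown encoding-type '", type, "'"))
    return(invisible(NULL))
  }
  if (!is.null(version) && !.version_ok(version)) {
    v$add(path, "enc/bad-version",
          paste0("encoding-version '", version, "' is not dotted numerals"))
  }
  switch(type,
    "csr_matrix" = .validate_sparse(h5, path, "CSR", at, v),
    "csc_matrix" = .validate_sparse(h5, path, "CSC", at, v),
    "categorical" = .validate_categorical(h5, path, at, v),
    "nullable-integer" = ,
    "nullable-boolean" = .validate_nullable(h5, path, v),
    "dataframe" = .validate_dataframe(h5, path, at, v),
    "dict" = ,
    "raw" = {
      for (k in .h5_children(h5, path)) {
        .validate_element(h5, paste0(path, "/", k), v)
      }
    },
    "string" = ,
    "numeric-scalar" = {
      if (length(.h5_dims(h5, path)) != 0L) {
        v$add(path, "scalar/rank", "scalar encoding on a non-scalar dataset")
      }
    },
    NULL
  )
  invisible(NULL)
}

.validate_sparse <- function(h5, path, orientation, at, v) {
  shape <- at[["shape"]]
  if (is.null(shape) || length(shape) != 2L) {
    v$add(path, "sparse/shape-missing",
          "sparse group lacks a 2-element shape attribute")
    return(invisible(NULL))
  }
  shape <- as.integer(shape)
  for (part in c("data", "indices", "indptr")) {
    if (!.h5_exists(h5, paste0(path, "/", part))) {
      v$add(path, "sparse/missing-child",
            paste0("missing dataset '", part, "'"))
      return(invisible(NULL))
    }
  }
  data_len <- .h5_dims(h5, paste0(path, "/data"))
  idx_len <- .h5_dims(h5, paste0(path, "/indices"))
  indptr <- .h5_read_dataset(h5, paste0(path, "/indptr"))
  major <- if (orientation == "CSR") shape[1] else shape[2]
  minor <- if (orientation == "CSR") shape[2] else shape[1]
  if (length(indptr) != major + 1L) {
    v$add(path, "sparse/indptr-length",
          sprintf("indptr length %d, expected %d", length(indptr),
                  major + 1L))
    return(invisible(NULL))
  }
  if (is.unsorted(indptr)) {
    v$add(path, "sparse/indptr-monotone", "indptr is not non-decreasing")
  }
  if (data_len != idx_len) {
    v$add(path, "sparse/length-mismatch",
          "data and indices differ in length")
  }
  if (indptr[1] != 0L || indptr[length(indptr)] != data_len) {
    v$add(path, "sparse/indptr-ends",
          "indptr must start at 0 and end at length(data)")
  }
  if (idx_len > 0L) {
    indices <- .h5_read_dataset(h5, paste0(path, "/indices"))
    if (min(indices) < 0L || max(indices) >= minor) {
      v$add(path, "sparse/index-range",
            sprintf("indices out of range [0, %d)", minor))
    }
  }
  invisible(NULL)
}

.validate_categorical <- function(h5, path, at, v) {
  for (part in c("codes", "categories")) {
    if (!.h5_exists(h5, paste0(path, "/", part))) {
      v$add(path, "categorical/missing-child",
            paste0("missing dataset '", part, "'"))
      return(invisible(NULL))
    }
  }
  codes <- .h5_read_dataset(h5, paste0(path, "/codes"))
  categories <- .h5_read_dataset(h5, paste0(path, "/categories"))
  if (anyDuplicated(categories)) {
    v$add(path, "categorical/duplicate-categories",
          "categories contain duplicates")
  }
  if (length(codes) > 0L &&
      (min(codes) < -1L || max(codes) >= length(categories))) {
    v$add(path, "categorical/code-range",
          sprintf("codes outside [-1, %d)", length(categories)))
  }
  invisible(NULL)
}

.validate_nullable <- function(h5, path, v) {
  for (part in c("values", "mask")) {
    if (!.h5_exists(h5, paste0(path, "/", part))) {
      v$add(path, "nullable/missing-child",
            paste0("missing dataset '", part, "'"))
      return(invisible(NULL))
    }
  }
  nv <- .h5_dims(h5, paste0(path, "/values"))
  nm <- .h5_dims(h5, paste0(path, "/mask"))
  if (!identical(nv, nm)) {
    v$add(path, "nullable/length-mismatch",
          sprintf("values length %d, mask length %d", nv, nm))
  }
  invisible(NULL)
}

.validate_dataframe <- function(h5, path, at, v) {
  index_name <- at[["_index"]]
  if (is.null(index_name)) {
    v$add(path, "dataframe/index-missing",
          "dataframe group has no _index attribute")
    return(invisible(NULL))
  }
  kids <- .h5_children(h5, path)
  if (!index_name %in% kids) {
    v$add(path, "dataframe/index-missing",
          paste0("index dataset '", index_name, "' is absent"))
    return(invisible(NULL))
  }
  col_order <- at[["column-order"]]
  if (is.null(col_order)) col_order <- character(0)
  col_order <- as.character(col_order)
  missing_cols <- setdiff(col_order, kids)
  if (length(missing_cols) > 0L) {
    v$add(path, "dataframe/column-order",
          paste0("column-order names absent columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  n <- .element_length(h5, paste0(path, "/", index_name))
  for (cn in intersect(col_order, kids)) {
    cp <- paste0(path, "/", cn)
    len <- .element_length(h5, cp)
    if (!is.na(len) && len != n) {
      v$add(cp, "dataframe/column-length",
            sprintf("column length %d does not match index length %d",
                    len, n))
    }
    .validate_element(h5, cp, v)
  }
  invisible(NULL)
}

# logical length of a column-like element (categorical/nullable use their
# codes/values child)
.element_length <- function(h5, path) {
  if (.h5_is_group(h5, path)) {
    kids <- .h5_children(h5, path)
    child <- if ("codes" %in% kids) "codes"
             else if ("values" %in% kids) "values"
             else return(NA_integer_)
    return(.h5_dims(h5, paste0(path, "/", child))[1])
  }
  d <- .h5_dims(h5, path)
  if (length(d) == 0L) return(1L)
  d[1]
}
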