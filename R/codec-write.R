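# Encoders: R values -> on-disk elements.
#
# Dispatch, mirroring the decoders in codec-read.R:
#   RsparseMatrix                  -> csr_matrix
#   CsparseMatrix / TsparseMatrix  -> csc_matrix
#   factor                         -> categorical
#   data.frame                     -> dataframe
#   named list                     -> dict (recursively)
#   integer/logical with NA        -> nullable-integer / nullable-boolean
#   character                      -> string-array (or string scalar)
#   other atomic vectors/arrays    -> array (or numeric-scalar)
#
# Scalar rule: inside mappings (uns and nested dicts) a length-1 atomic
# vector without a dim attribute encodes as a scalar; everywhere else
# (dataframe columns, matrix slots) values are written as arrays.

#' Write one element into an open H5AD file
#'
#' Encodes an R value at `path` per the AnnData on-disk specification,
#' stamping `encoding-type`/`encoding-version` attributes.
#'
#' @param x Value to encode (see the mapping table in the vignette).
#' @param file Path to an HDF5 file (created if absent) or an open writable
#'   rhdf5 handle.
#' @param path Element path to create. Must not already exist.
#' @param level Gzip compression level for datasets, 0 disables. Default 4.
#' @param scalarOK Whether a length-1 atomic value may be written with a
#'   scalar encoding (`TRUE` inside mappings).
#' @return Invisibly, `NULL`.
#' @export
writeElement <- function(x, file, path, level = 4L, scalarOK = FALSE) {
  if (is.character(file)) {
    if (!file.exists(file)) rhdf5::h5createFile(file)
    h5 <- rhdf5::H5Fopen(file)
    on.exit(.h5_close(h5))
  } else {
    h5 <- file
  }
  .write_element(x, h5, path, level = level, scalarOK = scalarOK)
}

.write_element <- function(x, h5, path, level = 4L, scalarOK = FALSE,
                           depth = 0L) {
  if (depth > 100L) {
    .h5ad_stop(path, "mapping nesting exceeds depth 100 (cycle?)")
  }
  if (is.null(x)) .h5ad_stop(path, "cannot encode NULL")
  if (is(x, "sparseMatrix")) {
    orientation <- if (is(x, "RsparseMatrix")) "CSR" else "CSC"
    return(.write_sparse(x, h5, path, orientation, level))
  }
  if (is.factor(x)) return(.write_categorical(x, h5, path, level))
  if (is.data.frame(x)) return(.write_dataframe(x, h5, path, level = level))
  if (is.list(x)) return(.write_mapping(x, h5, path, level, depth))
  if (is(x, "Matrix")) x <- as.matrix(x)   # dense Matrix classes
  if (!is.atomic(x)) {
    .h5ad_stop(path, paste0("cannot encode object of class '",
                            paste(class(x), collapse = "/"), "'"))
  }
  scalar <- scalarOK && length(x) == 1L && is.null(dim(x)) && !anyNA(x)
  if (is.character(x)) {
    type <- if (scalar) "string" else "string-array"
    .h5_write_dataset(h5, path, x, "string", level = level, scalar = scalar)
  } else if (is.logical(x)) {
    if (anyNA(x)) return(.write_nullable(x, h5, path, "boolean", level))
    type <- if (scalar) "numeric-scalar" else "array"
    .h5_write_dataset(h5, path, x, "bool", level = level, scalar = scalar)
  } else if (is.integer(x)) {
    if (anyNA(x)) return(.write_nullable(x, h5, path, "integer", level))
    type <- if (scalar) "numeric-scalar" else "array"
    .h5_write_dataset(h5, path, x, "integer", level = level, scalar = scalar)
  } else if (is.numeric(x)) {
    type <- if (scalar) "numeric-scalar" else "array"
    .h5_write_dataset(h5, path, x, "double", level = level, scalar = scalar)
  } else {
    .h5ad_stop(path, paste0("cannot encode atomic mode '", mode(x), "'"))
  }
  .write_encoding_attrs(h5, path, type)
  invisible(NULL)
}

# matrix may be a Matrix sparse class or a base dense matrix
.write_sparse <- function(m, h5, path, orientation = c("CSR", "CSC"),
                          level = 4L) {
  orientation <- match.arg(orientation)
  if (!is(m, "sparseMatrix")) {
    m <- Matrix::Matrix(as.matrix(m), sparse = TRUE)
  }
  if (orientation == "CSR") {
    m <- as(as(as(m, "dMatrix"), "generalMatrix"), "RsparseMatrix")
    indices <- m@j
    indptr <- m@p
  } else {
    m <- as(as(as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
    indices <- m@i
    indptr <- m@p
  }
  shape <- dim(m)
  if (anyNA(shape) || any(!is.finite(shape))) {
    .h5ad_stop(path, "sparse matrix has non-finite shape")
  }
  .h5_create_group(h5, path)
  .h5_write_dataset(h5, paste0(path, "/data"), as.double(m@x), "double",
                    level = level)
  .h5_write_dataset(h5, paste0(path, "/indices"), indices, "int64",
                    level = level)
  .h5_write_dataset(h5, paste0(path, "/indptr"), indptr, "int64",
                    level = level)
  .h5_write_attr(h5, path, "shape", as.integer(shape), scalar = FALSE)
  .write_encoding_attrs(
    h5, path, if (orientation == "CSR") "csr_matrix" else "csc_matrix")
  invisible(NULL)
}

.write_categorical <- function(f, h5, path, level = 4L) {
  codes <- as.integer(f) - 1L
  codes[is.na(codes)] <- -1L
  .h5_create_group(h5, path)
  .h5_write_dataset(h5, paste0(path, "/codes"), codes, "integer",
                    level = level)
  .write_encoding_attrs(h5, paste0(path, "/codes"), "array")
  .h5_write_dataset(h5, paste0(path, "/categories"), levels(f), "string",
                    level = level)
  .write_encoding_attrs(h5, paste0(path, "/categories"), "string-array")
  .h5_write_attr(h5, path, "ordered", is.ordered(f))
  .write_encoding_attrs(h5, path, "categorical")
  invisible(NULL)
}

.write_nullable <- function(x, h5, path, kind, level = 4L) {
  mask <- is.na(x)
  values <- x
  values[mask] <- if (kind == "integer") 0L else FALSE
  .h5_create_group(h5, path)
  .h5_write_dataset(h5, paste0(path, "/values"), values,
                    if (kind == "integer") "integer" else "bool",
                    level = level)
  .write_encoding_attrs(h5, paste0(path, "/values"), "array")
  .h5_write_dataset(h5, paste0(path, "/mask"), mask, "bool", level = level)
  .write_encoding_attrs(h5, paste0(path, "/mask"), "array")
  .write_encoding_attrs(
    h5, path, if (kind == "integer") "nullable-integer" else "nullable-boolean")
  invisible(NULL)
}

.write_dataframe <- function(df, h5, path, index = NULL, index_name = NULL,
                             level = 4L) {
  if (is.null(index)) {
    index <- attr(df, "h5ad_index")
    if (is.null(index)) index <- rownames(df)
    if (is.null(index)) index <- as.character(seq_len(nrow(df)) - 1L)
  }
  if (is.null(index_name)) {
    index_name <- attr(df, "h5ad_index_name")
    if (is.null(index_name)) index_name <- "_index"
  }
  cols <- names(df)
  if (anyDuplicated(cols)) {
    .h5ad_stop(path, paste0("duplicate column names: ",
                            paste(unique(cols[duplicated(cols)]),
                                  collapse = ", ")))
  }
  if (index_name %in% cols) {
    .h5ad_stop(path, paste0("column '", index_name,
                            "' collides with the index name"))
  }
  if (length(index) != nrow(df)) {
    .h5ad_stop(path, sprintf("index length %d does not match %d rows",
                             length(index), nrow(df)))
  }
  .h5_create_group(h5, path)
  .h5_write_dataset(h5, paste0(path, "/", index_name), as.character(index),
                    "string", level = level)
  .write_encoding_attrs(h5, paste0(path, "/", index_name), "string-array")
  for (cn in cols) {
    col <- df[[cn]]
    if (NROW(col) != nrow(df)) {
      .h5ad_stop(paste0(path, "/", cn), "column length mismatch")
    }
    .write_element(col, h5, paste0(path, "/", cn), level = level,
                   scalarOK = FALSE)
  }
  .h5_write_attr(h5, path, "_index", index_name)
  # a zero-length string attribute cannot be created through rhdf5; readers
  # treat a missing column-order as "no columns beyond the index"
  if (length(cols) > 0L) {
    .h5_write_attr(h5, path, "column-order", as.character(cols),
                   scalar = FALSE)
  }
  .write_encoding_attrs(h5, path, "dataframe")
  invisible(NULL)
}

.write_mapping <- function(x, h5, path, level = 4L, depth = 0L) {
  keys <- names(x)
  if (length(x) > 0L && (is.null(keys) || any(!nzchar(keys)))) {
    .h5ad_stop(path, "mappings require non-empty names for every entry")
  }
  if (anyDuplicated(keys)) {
    .h5ad_stop(path, "duplicate keys in mapping")
  }
  .h5_create_group(h5, path)
  for (k in keys) {
    .write_element(x[[k]], h5, paste0(path, "/", k), level = level,
                   scalarOK = TRUE, depth = depth + 1L)
  }
  .write_encoding_attrs(h5, path, "dict")
  invisible(NULL)
}
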