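# Decoders: on-disk elements -> R values.
#
# Decoded representations:
#   array            -> numeric/integer/logical/character vector or array
#   string-array     -> character vector
#   string           -> length-1 character
#   numeric-scalar   -> length-1 numeric/integer/logical
#   csr_matrix       -> Matrix::dgRMatrix
#   csc_matrix       -> Matrix::dgCMatrix
#   categorical      -> factor (ordered factor when flagged)
#   nullable-integer -> integer vector, masked entries NA
#   nullable-boolean -> logical vector, masked entries NA
#   dataframe        -> data.frame; attributes "h5ad_index" (character) and
#                       "h5ad_index_name"; rownames set when the index is
#                       unique (the format permits duplicates, R does not)
#   dict             -> named list

#' Read one encoded element from an H5AD file
#'
#' Decodes the element at `path` according to its `encoding-type` attribute
#' (see [encodingRegistry()] for the supported set and [detectEncoding()]
#' for the legacy policy).
#'
#' @inheritParams detectEncoding
#' @return The decoded R value; see the mapping table in the package
#'   vignette.
#' @export
readElement <- function(file, path, legacy = c("infer", "error")) {
  legacy <- match.arg(legacy)
  if (is.character(file)) {
    h5 <- .h5_open_ro(file)
    on.exit(.h5_close(h5))
  } else {
    h5 <- file
  }
  desc <- detectEncoding(h5, path, legacy = legacy)
  switch(desc$type,
    "array"            = .read_dense(h5, path),
    "string-array"     = .read_dense(h5, path),
    "string"           = .h5_read_dataset(h5, path),
    "numeric-scalar"   = .h5_read_dataset(h5, path),
    "csr_matrix"       = .read_sparse(h5, path, "CSR"),
    "csc_matrix"       = .read_sparse(h5, path, "CSC"),
    "categorical"      = .read_categorical(h5, path),
    "nullable-integer" = .read_nullable(h5, path, "integer"),
    "nullable-boolean" = .read_nullable(h5, path, "boolean"),
    "dataframe"        = .read_dataframe(h5, path, legacy),
    "dict"             = .read_mapping(h5, path, legacy),
    "raw"              = .read_mapping(h5, path, legacy),
    .h5ad_stop(path, sprintf("no decoder for encoding '%s'", desc$type))
  )
}

.read_dense <- function(h5, path) {
  .h5_read_dataset(h5, path)
}

.read_sparse <- function(h5, path, orientation) {
  at <- .h5_read_attrs(h5, path)
  shape <- as.integer(at[["shape"]])
  if (length(shape) != 2L || anyNA(shape) || any(shape < 0L)) {
    .h5ad_stop(path, "sparse matrix group lacks a valid shape attribute",
               "h5adkit_validation_error")
  }
  for (part in c("data", "indices", "indptr")) {
    if (!.h5_exists(h5, paste0(path, "/", part))) {
      .h5ad_stop(path, paste0("sparse matrix group is missing '", part, "'"),
                 "h5adkit_validation_error")
    }
  }
  data <- as.double(.h5_read_dataset(h5, paste0(path, "/data")))
  indices <- as.integer(.h5_read_dataset(h5, paste0(path, "/indices")))
  indptr <- as.integer(.h5_read_dataset(h5, paste0(path, "/indptr")))
  .check_sparse_triple(data, indices, indptr, shape, orientation, path)
  if (orientation == "CSR") {
    new("dgRMatrix", j = indices, p = indptr, x = data, Dim = shape)
  } else {
    new("dgCMatrix", i = indices, p = indptr, x = data, Dim = shape)
  }
}

# SparseTriple invariants; every violation is a path-addressed error
.check_sparse_triple <- function(data, indices, indptr, shape, orientation,
                                 path) {
  major <- if (orientation == "CSR") shape[1] else shape[2]
  minor <- if (orientation == "CSR") shape[2] else shape[1]
  if (length(indptr) != major + 1L) {
    .h5ad_stop(path, sprintf(
      "indptr has length %d, expected major dimension + 1 = %d",
      length(indptr), major + 1L), "h5adkit_validation_error")
  }
  if (length(data) != length(indices)) {
    .h5ad_stop(path, "data and indices differ in length",
               "h5adkit_validation_error")
  }
  if (length(indptr) == 0L || indptr[1] != 0L ||
      indptr[length(indptr)] != length(data)) {
    .h5ad_stop(path, "indptr must start at 0 and end at length(data)",
               "h5adkit_validation_error")
  }
  if (is.unsorted(indptr)) {
    .h5ad_stop(path, "indptr is not non-decreasing",
               "h5adkit_validation_error")
  }
  if (length(indices) > 0L && (min(indices) < 0L || max(indices) >= minor)) {
    .h5ad_stop(path, sprintf(
      "indices out of range [0, %d)", minor), "h5adkit_validation_error")
  }
  invisible(TRUE)
}

.read_categorical <- function(h5, path) {
  codes <- as.integer(.h5_read_dataset(h5, paste0(path, "/codes")))
  categories <- as.character(.h5_read_dataset(h5, paste0(path, "/categories")))
  at <- .h5_read_attrs(h5, path)
  ordered <- isTRUE(as.logical(at[["ordered"]]))
  if (anyDuplicated(categories)) {
    .h5ad_stop(path, "categorical categories contain duplicates",
               "h5adkit_validation_error")
  }
  if (length(codes) > 0L &&
      (min(codes) < -1L || max(codes) >= length(categories))) {
    .h5ad_stop(path, sprintf(
      "categorical codes out of range [-1, %d)", length(categories)),
      "h5adkit_validation_error")
  }
  idx <- codes + 1L
  idx[idx == 0L] <- NA_integer_   # code -1 = missing
  factor(categories[idx], levels = categories, ordered = ordered)
}

.read_nullable <- function(h5, path, kind) {
  values <- .h5_read_dataset(h5, paste0(path, "/values"))
  mask <- as.logical(.h5_read_dataset(h5, paste0(path, "/mask")))
  if (length(values) != length(mask)) {
    .h5ad_stop(path, sprintf(
      "values (%d) and mask (%d) differ in length",
      length(values), length(mask)), "h5adkit_validation_error")
  }
  values <- if (kind == "integer") as.integer(values) else as.logical(values)
  values[mask] <- NA
  values
}

.read_dataframe <- function(h5, path, legacy = "infer") {
  at <- .h5_read_attrs(h5, path)
  index_name <- at[["_index"]]
  if (is.null(index_name)) {
    .h5ad_stop(path, "dataframe group has no _index attribute",
               "h5adkit_validation_error")
  }
  kids <- .h5_children(h5, path)
  col_order <- at[["column-order"]]
  if (is.null(col_order)) {
    col_order <- setdiff(kids, index_name)   # legacy / zero-column tables
  }
  col_order <- as.character(col_order)       # empty attr may decode numeric
  missing_cols <- setdiff(col_order, kids)
  if (length(missing_cols) > 0L) {
    .h5ad_stop(path, paste0("column-order names absent columns: ",
                            paste(missing_cols, collapse = ", ")),
               "h5adkit_validation_error")
  }
  index <- as.character(readElement(h5, paste0(path, "/", index_name), legacy))
  cols <- lapply(col_order, function(cn) {
    readElement(h5, paste0(path, "/", cn), legacy)
  })
  names(cols) <- col_order
  bad <- vapply(cols, function(x) NROW(x) != length(index), logical(1))
  if (any(bad)) {
    .h5ad_stop(paste0(path, "/", col_order[bad][1]),
               sprintf("column length %d does not match index length %d",
                       NROW(cols[[which(bad)[1]]]), length(index)),
               "h5adkit_validation_error")
  }
  df <- data.frame(cols, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L && length(index) > 0L) {
    # 0-column table: give it the right number of rows
    df <- as.data.frame(matrix(nrow = length(index), ncol = 0))
  }
  if (!anyDuplicated(index) && length(index) > 0L) rownames(df) <- index
  attr(df, "h5ad_index") <- index
  attr(df, "h5ad_index_name") <- index_name
  df
}

.read_mapping <- function(h5, path, legacy = "infer") {
  kids <- .h5_children(h5, path)
  out <- lapply(kids, function(k) readElement(h5, paste0(path, "/", k), legacy))
  if (length(out) > 0L) names(out) <- kids
  out
}
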