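# Low-level helpers around rhdf5.
#
# All functions here work in *logical* (row = first axis) coordinates: a 2-d
# element with logical shape (n, m) -- the shape h5py reports -- is an R
# matrix with n rows. HDF5 stores row-major and R column-major, so every
# multi-dimensional read/write goes through aperm() with native = TRUE.

.h5state <- new.env(parent = emptyenv())
.h5state$dataset_reads <- character(0)

.log_dataset_read <- function(path) {
  .h5state$dataset_reads <- c(.h5state$dataset_reads, path)
  invisible(NULL)
}

#' Dataset read instrumentation
#'
#' Every decoded HDF5 dataset payload is recorded in an internal log. The log
#' exists so that laziness contracts (a file-backed container must not touch
#' matrix payloads when only metadata is accessed) can be asserted in tests.
#'
#' @param reset If `TRUE` (default), clear the log after returning it.
#' @return Character vector of dataset paths read since the last reset.
#' @export
datasetReadLog <- function(reset = TRUE) {
  log <- .h5state$dataset_reads
  if (reset) .h5state$dataset_reads <- character(0)
  log
}

.h5_open_ro <- function(path) {
  if (!file.exists(path)) {
    stop("file does not exist: '", path, "'", call. = FALSE)
  }
  if (!rhdf5::H5Fis_hdf5(path)) {
    stop("not an HDF5 file: '", path, "'", call. = FALSE)
  }
  rhdf5::H5Fopen(path, flags = "H5F_ACC_RDONLY")
}

.h5_close <- function(h5) {
  try(rhdf5::H5Fclose(h5), silent = TRUE)
  invisible(NULL)
}

.h5_exists <- function(h5, path) {
  path <- sub("^/", "", path)
  if (path == "") return(TRUE)
  # check each intermediate link so H5Lexists never errors
  parts <- strsplit(path, "/", fixed = TRUE)[[1]]
  cur <- ""
  for (p in parts) {
    cur <- if (cur == "") p else paste(cur, p, sep = "/")
    if (!rhdf5::H5Lexists(h5, cur)) return(FALSE)
  }
  TRUE
}

.h5_is_group <- function(h5, path) {
  oid <- rhdf5::H5Oopen(h5, path)
  on.exit(rhdf5::H5Oclose(oid))
  grepl("GROUP", rhdf5::H5Iget_type(oid))
}

.h5_children <- function(h5, path = "/") {
  gid <- rhdf5::H5Gopen(h5, path)
  on.exit(rhdf5::H5Gclose(gid))
  info <- rhdf5::h5ls(gid, recursive = FALSE)
  if (is.null(info) || nrow(info) == 0) return(character(0))
  info$name
}

# dclass of a dataset ("INTEGER", "FLOAT", "STRING", "ENUM", ...) looked up
# through the parent group listing; rhdf5 exposes no direct H5Tget_class.
.h5_dclass <- function(h5, path) {
  path <- sub("^/", "", path)
  parent <- dirname(path)
  if (parent == ".") parent <- "/"
  gid <- rhdf5::H5Gopen(h5, parent)
  on.exit(rhdf5::H5Gclose(gid))
  info <- rhdf5::h5ls(gid, recursive = FALSE)
  row <- info[info$name == basename(path), , drop = FALSE]
  if (nrow(row) == 0) stop("no such dataset: ", path, call. = FALSE)
  row$dclass[1]
}

# logical-order dims of a dataset; scalar (rank-0) datasets give integer(0)
.h5_dims <- function(h5, path) {
  did <- rhdf5::H5Dopen(h5, path)
  on.exit(rhdf5::H5Dclose(did))
  sid <- rhdf5::H5Dget_space(did)
  on.exit(rhdf5::H5Sclose(sid), add = TRUE, after = FALSE)
  ext <- rhdf5::H5Sget_simple_extent_dims(sid)
  if (ext$rank == 0) return(integer(0))
  # rhdf5 reports extents in R (column-major) order; flip to logical order
  rev(as.integer(ext$size))
}

.h5_read_attrs <- function(h5, path) {
  if (path %in% c("", "/")) {
    at <- rhdf5::h5readAttributes(h5, "/")
  } else {
    at <- rhdf5::h5readAttributes(h5, path)
  }
  # normalise enum/factor attributes to logical, drop 1-d dim attributes
  lapply(at, function(v) {
    if (is.factor(v) && all(levels(v) %in% c("FALSE", "TRUE"))) {
      v <- as.logical(as.character(v))
    }
    if (!is.null(dim(v)) && length(dim(v)) == 1L) dim(v) <- NULL
    v
  })
}

# Read a dataset payload into logical orientation.
# Returns the value; rank-0 datasets come back as plain length-1 vectors,
# rank-1 as plain vectors, rank >= 2 as arrays with logical dims.
.h5_read_dataset <- function(h5, path) {
  .log_dataset_read(path)
  dims <- .h5_dims(h5, path)
  dclass <- .h5_dclass(h5, path)
  x <- rhdf5::h5read(h5, path, native = TRUE, bit64conversion = "double")
  if (is.factor(x) && all(levels(x) %in% c("FALSE", "TRUE"))) {
    x <- as.logical(as.character(x))
  }
  if (dclass == "INTEGER" && is.double(x)) {
    # int64 came back as double; fold back to R integer when it fits
    ok <- length(x) == 0 ||
      all(is.na(x) | (abs(x) <= .Machine$integer.max & x == trunc(x)))
    if (ok) {
      storage.mode(x) <- "integer"
    } else {
      warning("64-bit integers at '", path,
              "' exceed R's integer range; returning doubles", call. = FALSE)
    }
  }
  if (length(dims) >= 2) {
    dim(x) <- rev(dims)
    x <- aperm(x)
  } else {
    dim(x) <- NULL
  }
  x
}

# ---- writing ---------------------------------------------------------------

.bool_enum_type <- function(base = "H5T_NATIVE_UCHAR") {
  tid <- rhdf5::H5Tenum_create(dtype_id = base)
  rhdf5::H5Tenum_insert(tid, "FALSE", 0L)
  rhdf5::H5Tenum_insert(tid, "TRUE", 1L)
  tid
}

.vlen_utf8_type <- function() {
  tid <- rhdf5::H5Tcopy("H5T_C_S1")
  rhdf5::H5Tset_size(tid, NULL)
  rhdf5::H5Tset_cset(tid, "UTF-8")
  tid
}

.strip_rhdf5_attr <- function(h5, path) {
  oid <- rhdf5::H5Oopen(h5, path)
  on.exit(rhdf5::H5Oclose(oid))
  if (rhdf5::H5Aexists(oid, "rhdf5-NA.OK")) rhdf5::H5Adelete(oid, "rhdf5-NA.OK")
  invisible(NULL)
}

.h5_create_group <- function(h5, path) {
  gid <- rhdf5::H5Gcreate(h5, path)
  rhdf5::H5Gclose(gid)
  invisible(NULL)
}

# gzip'd chunked dataset-creation property list (NULL when not compressing);
# `file_dims` must already be in file (row-major) order
.dcpl_for <- function(file_dims, level) {
  if (level <= 0 || any(file_dims == 0) || length(file_dims) == 0) return(NULL)
  dcpl <- rhdf5::H5Pcreate("H5P_DATASET_CREATE")
  rhdf5::H5Pset_chunk(dcpl, pmin(file_dims, 4096L))
  rhdf5::H5Pset_deflate(dcpl, level)
  dcpl
}

# Write a logical-orientation array `x` (vector, matrix or array) as a
# dataset. dtype: "double", "integer", "int64", "string", "bool".
.h5_write_dataset <- function(h5, path, x, dtype, level = 4L, scalar = FALSE) {
  if (scalar) {
    return(.h5_write_scalar(h5, path, x, dtype))
  }
  dims <- if (is.null(dim(x))) length(x) else dim(x)
  if (dtype == "string") {
    if (length(dims) > 1) {
      stop("multi-dimensional string datasets are not written", call. = FALSE)
    }
    chunk <- if (dims[1] > 0 && level > 0) pmin(dims, 4096L) else NULL
    rhdf5::h5createDataset(h5, path, dims = dims, storage.mode = "character",
                           size = NULL, encoding = "UTF-8",
                           level = if (is.null(chunk)) 0L else level,
                           chunk = chunk)
    if (dims[1] > 0) rhdf5::h5write(enc2utf8(x), h5, path)
  } else if (dtype == "bool") {
    ftid <- .bool_enum_type("H5T_NATIVE_UCHAR")
    mtid <- .bool_enum_type("H5T_NATIVE_INT")
    sid <- rhdf5::H5Screate_simple(rev(dims))
    dcpl <- .dcpl_for(rev(dims), level)
    did <- rhdf5::H5Dcreate(h5, path, ftid, sid, dcpl = dcpl)
    buf <- as.integer(if (length(dims) >= 2) aperm(x) else x)
    if (length(buf) > 0) rhdf5::H5Dwrite(did, buf, h5type = mtid)
    rhdf5::H5Dclose(did)
    rhdf5::H5Sclose(sid)
    if (!is.null(dcpl)) rhdf5::H5Pclose(dcpl)
  } else if (dtype == "int64") {
    if (length(dims) > 1) stop("int64 writer is 1-d only", call. = FALSE)
    chunk <- if (dims[1] > 0 && level > 0) pmin(dims, 65536L) else NULL
    rhdf5::h5createDataset(h5, path, dims = dims, H5type = "H5T_STD_I64LE",
                           level = if (is.null(chunk)) 0L else level,
                           chunk = chunk)
    if (dims[1] > 0) rhdf5::h5write(x, h5, path)
  } else {
    storage <- if (dtype == "integer") "integer" else "double"
    chunk <- if (all(dims > 0) && level > 0) pmin(dims, 4096L) else NULL
    # with native = TRUE, h5createDataset itself reverses `dims` to file
    # order, so pass rev() to end up with the logical shape on disk
    rhdf5::h5createDataset(h5, path, dims = rev(dims), storage.mode = storage,
                           level = if (is.null(chunk)) 0L else level,
                           chunk = if (is.null(chunk)) NULL else rev(chunk),
                           native = TRUE)
    if (all(dims > 0)) {
      obj <- if (length(dims) >= 2) aperm(x) else x
      rhdf5::h5write(obj, h5, path, native = TRUE)
    }
  }
  .strip_rhdf5_attr(h5, path)
  invisible(NULL)
}

.h5_write_scalar <- function(h5, path, value, dtype) {
  sid <- rhdf5::H5Screate("H5S_SCALAR")
  on.exit(rhdf5::H5Sclose(sid))
  if (dtype == "string") {
    tid <- .vlen_utf8_type()
    did <- rhdf5::H5Dcreate(h5, path, tid, sid)
    rhdf5::H5Dwrite(did, enc2utf8(as.character(value)))
    rhdf5::H5Dclose(did)
  } else if (dtype == "bool") {
    ftid <- .bool_enum_type("H5T_NATIVE_UCHAR")
    mtid <- .bool_enum_type("H5T_NATIVE_INT")
    did <- rhdf5::H5Dcreate(h5, path, ftid, sid)
    rhdf5::H5Dwrite(did, as.integer(value), h5type = mtid)
    rhdf5::H5Dclose(did)
  } else if (dtype == "integer") {
    did <- rhdf5::H5Dcreate(h5, path, "H5T_STD_I64LE", sid)
    rhdf5::H5Dwrite(did, as.integer(value))
    rhdf5::H5Dclose(did)
  } else {
    did <- rhdf5::H5Dcreate(h5, path, "H5T_IEEE_F64LE", sid)
    rhdf5::H5Dwrite(did, as.double(value))
    rhdf5::H5Dclose(did)
  }
  invisible(NULL)
}

# Attribute writer. `value` may be scalar string, string vector, integer
# vector, or scalar logical. Logical attributes are stored as int 0/1: the
# available HDF5 binding cannot write enum attributes, and the reference
# reader coerces flag attributes with bool(), so the deviation is benign
# (readers here normalise flag attributes back to logical).
.h5_write_attr <- function(h5, path, name, value, scalar = length(value) == 1L) {
  oid <- rhdf5::H5Oopen(h5, path)
  on.exit(rhdf5::H5Oclose(oid))
  if (is.logical(value)) {
    rhdf5::h5writeAttribute(as.integer(value), oid, name)
  } else if (is.character(value)) {
    rhdf5::h5writeAttribute(enc2utf8(value), oid, name,
                            variableLengthString = TRUE,
                            asScalar = scalar, encoding = "UTF-8")
  } else {
    rhdf5::h5writeAttribute(as.integer(value), oid, name)
  }
  invisible(NULL)
}
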