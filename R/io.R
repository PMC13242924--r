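.ROOT_SLOTS <- c("X", "layers", "obs", "var", "obsm", "varm",
                 "obsp", "varp", "uns", "raw")

# reserved uns key that receives unrecognized root children on read, so no
# data is silently dropped
.ORPHAN_KEY <- ".orphans"

#' Read an H5AD file
#'
#' Decodes an H5AD file into an in-memory [AnnData()] container, or returns
#' a lazily materialized [H5ADBacked] handle.
#'
#' Unrecognized children at the file root are not dropped: they are decoded
#' and retained under the reserved `uns` key `".orphans"`, with a warning.
#'
#' @param path Path to the H5AD file.
#' @param mode `"memory"` (default) decodes everything now; `"backed"`
#'   decodes metadata eagerly and leaves matrix slots on disk.
#' @param legacy Policy for elements without encoding attributes:
#'   `"infer"` (default, warns) or `"error"`.
#' @param include Optional character vector restricting which root slots
#'   are decoded (`obs` and `var` are always read).
#' @return An `AnnData` container or an `H5ADBacked` handle.
#' @seealso [writeH5AD()], [toMemory()]
#' @export
readH5AD <- function(path, mode = c("memory", "backed"),
                     legacy = c("infer", "error"), include = NULL) {
  mode <- match.arg(mode)
  legacy <- match.arg(legacy)
  if (mode == "backed") {
    return(.open_backed(path, legacy))
  }
  h5 <- .h5_open_ro(path)
  on.exit(.h5_close(h5))
  kids <- .h5_children(h5, "/")
  if (!all(c("obs", "var") %in% kids)) {
    stop("not an AnnData file (missing obs/var at the root): ", path,
         call. = FALSE)
  }
  keep <- function(slot) {
    is.null(include) || slot %in% include || slot %in% c("obs", "var")
  }
  rd <- function(p) readElement(h5, p, legacy)
  obs <- rd("obs")
  var <- rd("var")
  X <- if ("X" %in% kids && keep("X")) rd("X")
  slots <- list()
  for (sl in c("layers", "obsm", "varm", "obsp", "varp", "uns")) {
    slots[[sl]] <- if (sl %in% kids && keep(sl)) rd(sl) else list()
  }
  raw <- NULL
  if ("raw" %in% kids && keep("raw")) {
    rkids <- .h5_children(h5, "raw")
    raw <- list()
    if ("X" %in% rkids) raw$X <- rd("raw/X")
    if ("var" %in% rkids) {
      raw$var <- rd("raw/var")
      raw$varNames <- attr(raw$var, "h5ad_index")
    }
    if ("varm" %in% rkids) {
      vm <- rd("raw/varm")
      if (length(vm) > 0L) raw$varm <- vm
    }
  }
  orphans <- setdiff(kids, .ROOT_SLOTS)
  if (length(orphans) > 0L) {
    warning("unrecognized root element(s) retained under uns[['",
            .ORPHAN_KEY, "']]: ", paste(orphans, collapse = ", "),
            call. = FALSE)
    slots$uns[[.ORPHAN_KEY]] <- lapply(stats::setNames(orphans, orphans), rd)
  }
  AnnData(
    X = X,
    layers = slots$layers,
    obs = obs, var = var,
    obsNames = attr(obs, "h5ad_index"),
    varNames = attr(var, "h5ad_index"),
    obsm = slots$obsm, varm = slots$varm,
    obsp = slots$obsp, varp = slots$varp,
    uns = slots$uns,
    raw = raw
  )
}

#' Write an AnnData container to a new H5AD file
#'
#' Serializes the container per the AnnData on-disk specification. The
#' container is validated before any byte is written; the file is assembled
#' at a temporary path and atomically renamed on success, so a failed write
#' never leaves a partial file at `path`.
#'
#' The in-memory representation is kept on disk: sparse matrices stay
#' sparse in their orientation (`RsparseMatrix` as CSR, other sparse as
#' CSC), dense stays dense. Absent optional slots are omitted from the file
#' rather than written empty.
#'
#' @param ad An [AnnData()] container (a backed handle is materialized
#'   first).
#' @param path Target file path.
#' @param overwrite Refuse to replace an existing file unless `TRUE`.
#' @param compression `"gzip"` (default, level 4) or `"none"`.
#' @return Invisibly, `path`.
#' @export
writeH5AD <- function(ad, path, overwrite = FALSE,
                      compression = c("gzip", "none")) {
  compression <- match.arg(compression)
  level <- if (compression == "gzip") 4L else 0L
  if (is(ad, "H5ADBacked")) ad <- toMemory(ad)
  stopifnot(is(ad, "AnnData"))
  validateAnnData(ad)
  if (file.exists(path) && !overwrite) {
    stop("file exists (use overwrite = TRUE): '", path, "'", call. = FALSE)
  }
  tmp <- paste0(path, ".writing-", Sys.getpid())
  ok <- FALSE
  on.exit({
    if (!ok && file.exists(tmp)) unlink(tmp)
  })
  .write_h5ad_impl(ad, tmp, level)
  if (file.exists(path)) unlink(path)
  if (!file.rename(tmp, path)) {
    stop("could not move finished file to '", path, "'", call. = FALSE)
  }
  ok <- TRUE
  invisible(path)
}

.write_h5ad_impl <- function(ad, tmp, level) {
  e <- ad@.data
  rhdf5::h5createFile(tmp)
  h5 <- rhdf5::H5Fopen(tmp)
  on.exit(.h5_close(h5))
  .h5_write_attr(h5, "/", "encoding-type", "anndata")
  .h5_write_attr(h5, "/", "encoding-version", unname(.ENCODINGS[["anndata"]]))
  if (!is.null(e$X)) .write_matrix_slot(e$X, h5, "X", level)
  .write_dataframe(e$obs, h5, "obs", index = e$obsNames,
                   index_name = e$obsIndexName, level = level)
  .write_dataframe(e$var, h5, "var", index = e$varNames,
                   index_name = e$varIndexName, level = level)
  .write_axis_mapping(e$layers, h5, "layers", level, axis_names = NULL)
  .write_axis_mapping(e$obsm, h5, "obsm", level, axis_names = e$obsNames)
  .write_axis_mapping(e$varm, h5, "varm", level, axis_names = e$varNames)
  .write_axis_mapping(e$obsp, h5, "obsp", level, axis_names = NULL)
  .write_axis_mapping(e$varp, h5, "varp", level, axis_names = NULL)
  if (length(e$uns) > 0L) .write_mapping(e$uns, h5, "uns", level)
  if (!is.null(e$raw)) {
    .h5_create_group(h5, "raw")
    .write_encoding_attrs(h5, "raw", "raw")
    .write_matrix_slot(e$raw$X, h5, "raw/X", level)
    if (!is.null(e$raw$var)) {
      .write_dataframe(e$raw$var, h5, "raw/var", index = e$raw$varNames,
                       index_name = e$raw$varIndexName, level = level)
    }
    if (!is.null(e$raw$varm) && length(e$raw$varm) > 0L) {
      .write_axis_mapping(e$raw$varm, h5, "raw/varm", level,
                          axis_names = e$raw$varNames)
    }
  }
  invisible(NULL)
}

# X / layers entries: dense stays dense, sparse keeps its orientation
.write_matrix_slot <- function(m, h5, path, level) {
  if (is(m, "sparseMatrix")) {
    .write_sparse(m, h5, path,
                  if (is(m, "RsparseMatrix")) "CSR" else "CSC", level)
  } else {
    .write_element(as.matrix(m), h5, path, level = level)
  }
}

# obsm/varm/obsp/varp: dict group; data.frame entries inherit the axis
# names as their index when they do not carry one
.write_axis_mapping <- function(x, h5, path, level, axis_names) {
  if (length(x) == 0L) return(invisible(NULL))
  .h5_create_group(h5, path)
  .write_encoding_attrs(h5, path, "dict")
  for (k in names(x)) {
    v <- x[[k]]
    if (is.data.frame(v) && is.null(attr(v, "h5ad_index")) &&
        !is.null(axis_names)) {
      attr(v, "h5ad_index") <- axis_names
    }
    .write_element(v, h5, paste0(path, "/", k), level = level)
  }
  invisible(NULL)
}
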