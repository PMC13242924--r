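#' The AnnData container
#'
#' An annotated observations-by-variables data container: a central matrix
#' `X` (n_obs x n_var; cells in rows, features in columns, the AnnData
#' orientation) plus aligned metadata slots. The object wraps an
#' environment, so it has reference semantics: every handle to the same
#' container sees mutations made through any other handle, matching the
#' behaviour of the Python implementation.
#'
#' Slot shapes (all enforced by [validateAnnData()]):
#' * `X`, every `layers` entry: n_obs x n_var
#' * `obs`: data.frame with n_obs rows; `var`: n_var rows
#' * `obsm`/`varm` entries: first dimension n_obs / n_var
#' * `obsp`/`varp` entries: n_obs x n_obs / n_var x n_var
#' * `raw`: optional list with `X` (n_obs x n_var_raw), `var`, `varNames`
#'   and `varm` over a possibly different variable set (pre-filtering state)
#'
#' Duplicate `obsNames`/`varNames` are permitted (the on-disk format allows
#' them); converters repair them only where the target ecosystem requires.
#'
#' @param X Optional matrix-like (base matrix or `Matrix` sparse class).
#' @param obs,var Optional data.frames of per-observation / per-variable
#'   metadata. Rownames, when present and unique, seed `obsNames`/`varNames`.
#' @param layers,obsm,varm,obsp,varp Named lists of aligned elements.
#' @param uns Arbitrarily nested named list of unstructured metadata.
#' @param raw Optional list with elements `X`, `var`, `varNames`, `varm`.
#' @param obsNames,varNames Character vectors of axis names.
#' @param shape Optional `c(n_obs, n_var)` for containers with no
#'   dimension-bearing slot.
#' @return An `AnnData` object.
#' @aliases AnnData-class
#' @export
#' @examples
#' ad <- AnnData(
#'   X = matrix(0, 3, 5),
#'   obs = data.frame(group = c("a", "b", "a"), row.names = paste0("c", 1:3)),
#'   var = data.frame(row.names = paste0("g", 1:5))
#' )
#' dim(ad)
AnnData <- function(X = NULL, obs = NULL, var = NULL, layers = list(),
                    obsm = list(), varm = list(), obsp = list(),
                    varp = list(), uns = list(), raw = NULL,
                    obsNames = NULL, varNames = NULL, shape = NULL) {
  e <- new.env(parent = emptyenv())
  # the on-disk index column name travels with the container, not the table
  e$obsIndexName <- attr(obs, "h5ad_index_name") %||% "_index"
  e$varIndexName <- attr(var, "h5ad_index_name") %||% "_index"
  if (!is.null(raw) && !is.null(raw$var)) {
    raw$varIndexName <- raw$varIndexName %||%
      attr(raw$var, "h5ad_index_name") %||% "_index"
    raw$var <- .as_axis_table(raw$var, nrow(raw$var))
  }
  n_obs <- .first_non_null(
    if (!is.null(X)) nrow(X),
    if (!is.null(obs)) nrow(obs),
    if (!is.null(obsNames)) length(obsNames),
    if (length(layers)) nrow(layers[[1]]),
    if (!is.null(shape)) shape[1],
    0L)
  n_var <- .first_non_null(
    if (!is.null(X)) ncol(X),
    if (!is.null(var)) nrow(var),
    if (!is.null(varNames)) length(varNames),
    if (length(layers)) ncol(layers[[1]]),
    if (!is.null(shape)) shape[2],
    0L)
  e$n_obs <- as.integer(n_obs)
  e$n_var <- as.integer(n_var)
  e$X <- X
  e$layers <- layers
  e$obs <- .as_axis_table(obs, e$n_obs)
  e$var <- .as_axis_table(var, e$n_var)
  e$obsNames <- .resolve_axis_names(obsNames, obs, e$n_obs)
  e$varNames <- .resolve_axis_names(varNames, var, e$n_var)
  e$obsm <- obsm
  e$varm <- varm
  e$obsp <- obsp
  e$varp <- varp
  e$uns <- uns
  e$raw <- raw
  out <- new("AnnData", .data = e)
  validateAnnData(out)
  out
}

setClass("AnnData", representation(.data = "environment"))

.first_non_null <- function(...) {
  for (v in list(...)) if (!is.null(v)) return(v)
  NULL
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# normalise an axis metadata table: data.frame with the right row count, no
# semantic rownames (names live in obsNames/varNames) and no codec
# attributes (the index name lives on the container)
.as_axis_table <- function(df, n) {
  if (is.null(df)) {
    return(as.data.frame(matrix(nrow = n, ncol = 0)))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  attr(df, "h5ad_index") <- NULL
  attr(df, "h5ad_index_name") <- NULL
  df
}

.resolve_axis_names <- function(explicit, df, n) {
  if (!is.null(explicit)) return(as.character(explicit))
  if (!is.null(df)) {
    idx <- attr(df, "h5ad_index")
    if (!is.null(idx)) return(as.character(idx))
    rn <- rownames(df)
    if (!is.null(rn) && !identical(rn, as.character(seq_len(nrow(df))))) {
      return(rn)
    }
  }
  as.character(seq_len(n) - 1L)   # reference-style default index
}

# ---- validation ------------------------------------------------------------

.dim_of <- function(x) {
  d <- dim(x)
  if (is.null(d)) c(NROW(x), NCOL(x)) else d
}

.check_named_list <- function(x, slot) {
  if (!is.list(x)) return(sprintf("%s: must be a named list", slot))
  if (length(x) > 0L && (is.null(names(x)) || any(!nzchar(names(x))))) {
    return(sprintf("%s: every entry must be named", slot))
  }
  NULL
}

# Returns character(0) when valid, otherwise one message per violation,
# each naming the offending slot (first one is what validateAnnData throws).
.anndata_violations <- function(e) {
  msgs <- character(0)
  add <- function(m) msgs <<- c(msgs, m)
  no <- e$n_obs; nv <- e$n_var
  if (!is.null(e$X)) {
    d <- .dim_of(e$X)
    if (!identical(as.integer(d), c(no, nv))) {
      add(sprintf("X: expected %d x %d, got %d x %d", no, nv, d[1], d[2]))
    }
  }
  for (sl in c("layers", "obsm", "varm", "obsp", "varp")) {
    m <- .check_named_list(e[[sl]], sl)
    if (!is.null(m)) { add(m); next }
  }
  for (nm in names(e$layers)) {
    d <- .dim_of(e$layers[[nm]])
    if (!identical(as.integer(d), c(no, nv))) {
      add(sprintf("layers[%s]: expected %d x %d, got %d x %d",
                  nm, no, nv, d[1], d[2]))
    }
  }
  if (!is.data.frame(e$obs) || nrow(e$obs) != no) {
    add(sprintf("obs: expected a data.frame with %d rows", no))
  }
  if (!is.data.frame(e$var) || nrow(e$var) != nv) {
    add(sprintf("var: expected a data.frame with %d rows", nv))
  }
  if (length(e$obsNames) != no) {
    add(sprintf("obsNames: length %d, expected %d", length(e$obsNames), no))
  }
  if (length(e$varNames) != nv) {
    add(sprintf("varNames: length %d, expected %d", length(e$varNames), nv))
  }
  for (nm in names(e$obsm)) {
    if (NROW(e$obsm[[nm]]) != no) {
      add(sprintf("obsm[%s]: first dimension %d, expected n_obs = %d",
                  nm, NROW(e$obsm[[nm]]), no))
    }
  }
  for (nm in names(e$varm)) {
    if (NROW(e$varm[[nm]]) != nv) {
      add(sprintf("varm[%s]: first dimension %d, expected n_var = %d",
                  nm, NROW(e$varm[[nm]]), nv))
    }
  }
  for (nm in names(e$obsp)) {
    d <- .dim_of(e$obsp[[nm]])
    if (!identical(as.integer(d), c(no, no))) {
      add(sprintf("obsp[%s]: expected %d x %d", nm, no, no))
    }
  }
  for (nm in names(e$varp)) {
    d <- .dim_of(e$varp[[nm]])
    if (!identical(as.integer(d), c(nv, nv))) {
      add(sprintf("varp[%s]: expected %d x %d", nm, nv, nv))
    }
  }
  if (!is.list(e$uns)) add("uns: must be a list")
  if (!is.null(e$raw)) {
    r <- e$raw
    if (!is.list(r) || is.null(r$X)) {
      add("raw: must be a list with at least an X matrix")
    } else {
      d <- .dim_of(r$X)
      if (d[1] != no) {
        add(sprintf("raw: X has %d rows, expected n_obs = %d", d[1], no))
      }
      if (!is.null(r$var) && nrow(r$var) != d[2]) {
        add(sprintf("raw: var has %d rows, expected %d", nrow(r$var), d[2]))
      }
      if (!is.null(r$varNames) && length(r$varNames) != d[2]) {
        add("raw: varNames length does not match raw X columns")
      }
      for (nm in names(r$varm)) {
        if (NROW(r$varm[[nm]]) != d[2]) {
          add(sprintf("raw: varm[%s] first dimension mismatch", nm))
        }
      }
    }
  }
  msgs
}

#' Validate an AnnData container
#'
#' Asserts every shape invariant of the container; the error names the
#' first violated slot together with the expected and actual dimensions.
#'
#' @param object An `AnnData` object.
#' @return Invisibly `TRUE`; errors on the first violation.
#' @export
validateAnnData <- function(object) {
  msgs <- .anndata_violations(object@.data)
  if (length(msgs) > 0L) {
    stop("invalid AnnData: ", msgs[1], call. = FALSE)
  }
  invisible(TRUE)
}

setValidity("AnnData", function(object) {
  msgs <- .anndata_violations(object@.data)
  if (length(msgs) == 0L) TRUE else msgs
})

# ---- accessors -------------------------------------------------------------

#' @rdname h5adkit-accessors
setMethod("adX", "AnnData", function(x) x@.data$X)
#' @rdname h5adkit-accessors
setMethod("adLayers", "AnnData", function(x) x@.data$layers)
#' @rdname h5adkit-accessors
setMethod("adObs", "AnnData", function(x) {
  df <- x@.data$obs
  nm <- x@.data$obsNames
  if (!anyDuplicated(nm) && nrow(df) > 0L) rownames(df) <- nm
  df
})
#' @rdname h5adkit-accessors
setMethod("adVar", "AnnData", function(x) {
  df <- x@.data$var
  nm <- x@.data$varNames
  if (!anyDuplicated(nm) && nrow(df) > 0L) rownames(df) <- nm
  df
})
#' @rdname h5adkit-accessors
setMethod("adObsm", "AnnData", function(x) x@.data$obsm)
#' @rdname h5adkit-accessors
setMethod("adVarm", "AnnData", function(x) x@.data$varm)
#' @rdname h5adkit-accessors
setMethod("adObsp", "AnnData", function(x) x@.data$obsp)
#' @rdname h5adkit-accessors
setMethod("adVarp", "AnnData", function(x) x@.data$varp)
#' @rdname h5adkit-accessors
setMethod("adUns", "AnnData", function(x) x@.data$uns)
#' @rdname h5adkit-accessors
setMethod("adRaw", "AnnData", function(x) x@.data$raw)
#' @rdname h5adkit-accessors
setMethod("obsNames", "AnnData", function(x) x@.data$obsNames)
#' @rdname h5adkit-accessors
setMethod("varNames", "AnnData", function(x) x@.data$varNames)
#' @rdname h5adkit-accessors
setMethod("nObs", "AnnData", function(x) x@.data$n_obs)
#' @rdname h5adkit-accessors
setMethod("nVar", "AnnData", function(x) x@.data$n_var)

#' @export
setMethod("dim", "AnnData", function(x) c(x@.data$n_obs, x@.data$n_var))
#' @export
setMethod("dimnames", "AnnData", function(x) {
  list(x@.data$obsNames, x@.data$varNames)
})

# slot replacement with immediate re-validation; on failure the previous
# value is restored, so a container can never be observed in a broken state
.set_slot <- function(x, field, value) {
  e <- x@.data
  old <- e[[field]]
  e[[field]] <- value
  msgs <- .anndata_violations(e)
  if (length(msgs) > 0L) {
    e[[field]] <- old
    stop("invalid replacement: ", msgs[1], call. = FALSE)
  }
  x
}

#' @rdname h5adkit-accessors
setMethod("adX<-", "AnnData", function(x, value) .set_slot(x, "X", value))
#' @rdname h5adkit-accessors
setMethod("adLayers<-", "AnnData",
          function(x, value) .set_slot(x, "layers", value))
#' @rdname h5adkit-accessors
setMethod("adObs<-", "AnnData", function(x, value) {
  .set_slot(x, "obs", .as_axis_table(value, NROW(value)))
})
#' @rdname h5adkit-accessors
setMethod("adVar<-", "AnnData", function(x, value) {
  .set_slot(x, "var", .as_axis_table(value, NROW(value)))
})
#' @rdname h5adkit-accessors
setMethod("adObsm<-", "AnnData", function(x, value) .set_slot(x, "obsm", value))
#' @rdname h5adkit-accessors
setMethod("adVarm<-", "AnnData", function(x, value) .set_slot(x, "varm", value))
#' @rdname h5adkit-accessors
setMethod("adObsp<-", "AnnData", function(x, value) .set_slot(x, "obsp", value))
#' @rdname h5adkit-accessors
setMethod("adVarp<-", "AnnData", function(x, value) .set_slot(x, "varp", value))
#' @rdname h5adkit-accessors
setMethod("adUns<-", "AnnData", function(x, value) .set_slot(x, "uns", value))
#' @rdname h5adkit-accessors
setMethod("adRaw<-", "AnnData", function(x, value) .set_slot(x, "raw", value))
#' @rdname h5adkit-accessors
setMethod("obsNames<-", "AnnData",
          function(x, value) .set_slot(x, "obsNames", as.character(value)))
#' @rdname h5adkit-accessors
setMethod("varNames<-", "AnnData",
          function(x, value) .set_slot(x, "varNames", as.character(value)))

#' @export
setMethod("show", "AnnData", function(object) {
  e <- object@.data
  cat(sprintf("AnnData object with n_obs x n_var = %d x %d\n",
              e$n_obs, e$n_var))
  cat(sprintf("    X: %s\n",
              if (is.null(e$X)) "<absent>" else class(e$X)[1]))
  for (sl in c("layers", "obsm", "varm", "obsp", "varp")) {
    if (length(e[[sl]]) > 0L) {
      cat(sprintf("    %s: %s\n", sl, paste(names(e[[sl]]), collapse = ", ")))
    }
  }
  if (ncol(e$obs) > 0L) {
    cat("    obs:", paste(names(e$obs), collapse = ", "), "\n")
  }
  if (ncol(e$var) > 0L) {
    cat("    var:", paste(names(e$var), collapse = ", "), "\n")
  }
  if (length(e$uns) > 0L) {
    cat("    uns:", paste(names(e$uns), collapse = ", "), "\n")
  }
  if (!is.null(e$raw)) {
    cat(sprintf("    raw: %d variables\n", ncol(e$raw$X)))
  }
  invisible(NULL)
})

# ---- subsetting ------------------------------------------------------------

.resolve_selector <- function(sel, nms, n, axis) {
  if (is.null(sel)) return(seq_len(n))
  if (is.logical(sel)) {
    if (length(sel) != n) {
      stop(axis, " selector: logical length ", length(sel),
           " does not match ", n, call. = FALSE)
    }
    return(which(sel))
  }
  if (is.character(sel)) {
    idx <- match(sel, nms)
    if (anyNA(idx)) {
      stop(axis, " selector: unknown name(s): ",
           paste(sel[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    return(idx)
  }
  sel <- as.integer(sel)
  if (length(sel) > 0L && (min(sel) < 1L || max(sel) > n)) {
    stop(axis, " selector: index out of range 1..", n, call. = FALSE)
  }
  sel
}

.subset_first_dim <- function(x, i) {
  if (is.null(dim(x))) x[i] else x[i, , drop = FALSE]
}

#' Subset an AnnData container
#'
#' `x[i, j]` slices every slot consistently: `X` and `layers` on both axes,
#' `obs`/`obsm` rows and `obsp` rows *and* columns by `i`, `var`/`varm`
#' rows and `varp` both axes by `j`. `uns` passes through unchanged; `raw`
#' keeps all its variables (only observations are sliced). Selectors may be
#' integer indices, logical masks, or names resolved against
#' `obsNames`/`varNames`. Returns a new container.
#'
#' @param x An `AnnData` object.
#' @param i,j Observation and variable selectors.
#' @param ... Ignored.
#' @param drop Ignored (always `FALSE`).
#' @export
setMethod("[", "AnnData", function(x, i, j, ..., drop = FALSE) {
  e <- x@.data
  oi <- .resolve_selector(if (missing(i)) NULL else i,
                          e$obsNames, e$n_obs, "obs")
  vj <- .resolve_selector(if (missing(j)) NULL else j,
                          e$varNames, e$n_var, "var")
  sub2 <- function(m) if (is.null(m)) NULL else m[oi, vj, drop = FALSE]
  raw <- e$raw
  if (!is.null(raw)) {
    raw$X <- raw$X[oi, , drop = FALSE]
  }
  out <- AnnData(
    X = sub2(e$X),
    layers = lapply(e$layers, sub2),
    obs = e$obs[oi, , drop = FALSE],
    var = e$var[vj, , drop = FALSE],
    obsNames = e$obsNames[oi],
    varNames = e$varNames[vj],
    obsm = lapply(e$obsm, .subset_first_dim, i = oi),
    varm = lapply(e$varm, .subset_first_dim, i = vj),
    obsp = lapply(e$obsp, function(m) m[oi, oi, drop = FALSE]),
    varp = lapply(e$varp, function(m) m[vj, vj, drop = FALSE]),
    uns = e$uns,
    raw = raw
  )
  out@.data$obsIndexName <- e$obsIndexName
  out@.data$varIndexName <- e$varIndexName
  out
})
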