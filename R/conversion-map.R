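#' Conversion maps and loss reports
#'
#' A `ConversionMap` records, for one conversion direction, where each
#' AnnData slot goes in the target layout: the default destination token,
#' a custom name (for keyed entries such as `obsm:X_pca`), or `"DROP"`.
#' A `LossReport` documents everything a conversion could not place in a
#' first-class slot of the target: entries `dropped` (slot, reason),
#' `stashed` (slot, destination path) and `renamed` (old, new). Every
#' populated source slot not represented in the output appears in
#' `dropped` or `stashed` — nothing is silently lost.
#'
#' @name conversion-maps
#' @aliases ConversionMap-class LossReport-class
NULL

setClass("ConversionMap",
         representation(direction = "character", entries = "character",
                        unmappedPolicy = "character"))

setClass("LossReport",
         representation(dropped = "data.frame", stashed = "data.frame",
                        renamed = "data.frame"))

# reserved key that receives stashed slots in the target's metadata/misc
.STASH_KEY <- ".unmapped"

.DIRECTIONS <- c("to_sce", "from_sce", "to_seurat", "from_seurat")

.DEFAULT_ENTRIES <- list(
  to_sce = c(
    X = "assays", layers = "assays", obs = "colData", var = "rowData",
    obsm = "reducedDims", varm = "reducedDims", obsp = "colPairs",
    varp = "rowPairs", uns = "metadata", raw = "altExp"
  ),
  to_seurat = c(
    X = "layers", layers = "layers", obs = "meta.data",
    var = "assay-meta.data", obsm = "reductions", varm = "reductions",
    obsp = "graphs", varp = "STASH", uns = "misc", raw = "STASH"
  )
)
.DEFAULT_ENTRIES$from_sce <- .DEFAULT_ENTRIES$to_sce
.DEFAULT_ENTRIES$from_seurat <- .DEFAULT_ENTRIES$to_seurat

.VALID_DESTS <- list(
  to_sce = c("assays", "colData", "rowData", "reducedDims", "colPairs",
             "rowPairs", "metadata", "altExp", "STASH", "DROP"),
  to_seurat = c("layers", "meta.data", "assay-meta.data", "reductions",
                "graphs", "misc", "STASH", "DROP")
)
.VALID_DESTS$from_sce <- .VALID_DESTS$to_sce
.VALID_DESTS$from_seurat <- .VALID_DESTS$to_seurat

setValidity("ConversionMap", function(object) {
  if (!object@direction %in% .DIRECTIONS) {
    return(paste0("direction must be one of ",
                  paste(.DIRECTIONS, collapse = ", ")))
  }
  slots <- names(.DEFAULT_ENTRIES[[object@direction]])
  top <- names(object@entries)[!grepl(":", names(object@entries))]
  if (!all(slots %in% top)) {
    return(paste0("every AnnData slot must appear exactly once; missing: ",
                  paste(setdiff(slots, top), collapse = ", ")))
  }
  if (anyDuplicated(names(object@entries))) {
    return("duplicate entries in map")
  }
  valid <- .VALID_DESTS[[object@direction]]
  bad <- setdiff(unname(object@entries[top]), valid)
  if (length(bad) > 0L) {
    return(paste0("invalid destination token(s) for ", object@direction,
                  ": ", paste(bad, collapse = ", ")))
  }
  if (!object@unmappedPolicy %in%
      c("warn_and_stash", "warn_and_drop", "error")) {
    return("unknown unmappedPolicy")
  }
  TRUE
})

#' Default slot mapping for a conversion direction
#'
#' Returns the standard correspondence between AnnData slots and the
#' target layout: for SCE targets, `X`/`layers` to `assays`, `obs` to
#' `colData`, `var` to `rowData`, `obsm`/`varm` to `reducedDims`, `obsp`
#' to `colPairs`, `varp` to `rowPairs`, `uns` to `metadata` and `raw` to
#' an `altExp`; for Seurat targets, `X`/`layers` to assay layers, `obs`
#' to cell-level metadata, `var` to assay-level metadata, `obsm`/`varm`
#' to reductions, `obsp` to graphs and `uns` to `misc`. Seurat has no
#' first-class slot for `varp` (or for `raw`), so those default to the
#' documented stash under `misc[[".unmapped"]]`.
#'
#' @param direction One of `"to_sce"`, `"from_sce"`, `"to_seurat"`,
#'   `"from_seurat"`.
#' @param overrides Named character vector overriding defaults. Names are
#'   slot tokens (`"varp"`) or keyed entries (`"obsm:X_pca"`); values are a
#'   destination token, a custom destination name (keyed entries only), or
#'   `"DROP"`.
#' @param unmappedPolicy What to do with source content that has no
#'   destination: `"warn_and_stash"` (default), `"warn_and_drop"`,
#'   or `"error"`.
#' @return A `ConversionMap`.
#' @export
#' @examples
#' defaultMap("to_sce")
#' defaultMap("to_seurat", overrides = c("obsm:X_pca" = "pca_custom"))
defaultMap <- function(direction = .DIRECTIONS, overrides = NULL,
                       unmappedPolicy = c("warn_and_stash", "warn_and_drop",
                                          "error")) {
  direction <- match.arg(direction)
  unmappedPolicy <- match.arg(unmappedPolicy)
  entries <- .DEFAULT_ENTRIES[[direction]]
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides)))) {
      stop("overrides must be a fully named character vector", call. = FALSE)
    }
    top <- !grepl(":", names(overrides))
    bad <- setdiff(names(overrides)[top], names(entries))
    if (length(bad) > 0L) {
      stop("unknown slot token(s) in overrides: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    entries[names(overrides)] <- overrides
  }
  new("ConversionMap", direction = direction, entries = entries,
      unmappedPolicy = unmappedPolicy)
}

# destination for a keyed entry such as obsm:X_pca: a keyed override wins,
# then the slot-level entry
.map_dest <- function(map, slot, key = NULL) {
  if (!is.null(key)) {
    keyed <- paste0(slot, ":", key)
    if (keyed %in% names(map@entries)) return(unname(map@entries[[keyed]]))
  }
  unname(map@entries[[slot]])
}

#' @export
setMethod("show", "ConversionMap", function(object) {
  cat("ConversionMap <", object@direction, "> (unmapped: ",
      object@unmappedPolicy, ")\n", sep = "")
  e <- object@entries
  for (nm in names(e)) cat(sprintf("  %-12s -> %s\n", nm, e[nm]))
  invisible(NULL)
})

# ---- loss reports ----------------------------------------------------------

.empty_report <- function() {
  new("LossReport",
      dropped = data.frame(slot = character(0), reason = character(0),
                           stringsAsFactors = FALSE),
      stashed = data.frame(slot = character(0), destination = character(0),
                           stringsAsFactors = FALSE),
      renamed = data.frame(old = character(0), new = character(0),
                           stringsAsFactors = FALSE))
}

.report_drop <- function(rep, slot, reason) {
  rep@dropped <- rbind(rep@dropped,
                       data.frame(slot = slot, reason = reason,
                                  stringsAsFactors = FALSE))
  rep
}

.report_stash <- function(rep, slot, destination) {
  rep@stashed <- rbind(rep@stashed,
                       data.frame(slot = slot, destination = destination,
                                  stringsAsFactors = FALSE))
  rep
}

.report_rename <- function(rep, old, new) {
  rep@renamed <- rbind(rep@renamed,
                       data.frame(old = old, new = new,
                                  stringsAsFactors = FALSE))
  rep
}

#' @export
setMethod("show", "LossReport", function(object) {
  cat("LossReport:",
      nrow(object@dropped), "dropped,",
      nrow(object@stashed), "stashed,",
      nrow(object@renamed), "renamed\n")
  if (nrow(object@dropped) > 0L) {
    for (k in seq_len(nrow(object@dropped))) {
      cat("  dropped ", object@dropped$slot[k], ": ",
          object@dropped$reason[k], "\n", sep = "")
    }
  }
  if (nrow(object@stashed) > 0L) {
    for (k in seq_len(nrow(object@stashed))) {
      cat("  stashed ", object@stashed$slot[k], " -> ",
          object@stashed$destination[k], "\n", sep = "")
    }
  }
  if (nrow(object@renamed) > 0L) {
    for (k in seq_len(nrow(object@renamed))) {
      cat("  renamed ", object@renamed$old[k], " -> ",
          object@renamed$new[k], "\n", sep = "")
    }
  }
  invisible(NULL)
})

#' Accessors for LossReport contents
#'
#' @param x A `LossReport`.
#' @return A data.frame.
#' @name lossreport-accessors
NULL

#' @rdname lossreport-accessors
#' @export
reportDropped <- function(x) x@dropped
#' @rdname lossreport-accessors
#' @export
reportStashed <- function(x) x@stashed
#' @rdname lossreport-accessors
#' @export
reportRenamed <- function(x) x@renamed

#' @rdname lossReport
setMethod("lossReport", "ANY", function(x) attr(x, "lossReport"))

.attach_report <- function(obj, rep) {
  attr(obj, "lossReport") <- rep
  obj
}

# Pairwise matrices travel through the target's pairs/graphs interface as
# column-sparse matrices; the original representation (row-sparse or dense)
# is recorded so the inverse conversion restores it exactly.
.pair_encoding_of <- function(m) {
  if (is(m, "RsparseMatrix")) {
    "csr"
  } else if (is(m, "sparseMatrix")) {
    "csc"
  } else if (is.integer(m)) {
    "dense-integer"
  } else {
    "dense"
  }
}

.restore_pair_encoding <- function(m, enc) {
  if (is.null(enc) || enc == "csc") return(m)
  if (enc == "csr") {
    as(as(m, "generalMatrix"), "RsparseMatrix")
  } else {
    m <- unname(as.matrix(m))
    if (enc == "dense-integer") storage.mode(m) <- "integer"
    m
  }
}
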