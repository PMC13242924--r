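# AnnData <-> SingleCellExperiment.
#
# Orientation: AnnData stores cells x genes; SCE stores genes x cells, so
# every matrix slot is transposed on the way over and back. Matrices are
# moved with withDimnames = FALSE so the transfer is exactly invertible;
# axis names travel through colData/rowData rownames.

.strip_dimnames <- function(m) {
  if (is(m, "Matrix")) {
    m@Dimnames <- list(NULL, NULL)
  } else if (!is.null(attr(m, "dimnames"))) {
    attr(m, "dimnames") <- NULL
  }
  m
}

.policy_unmapped <- function(rep, policy, slot, dest_desc, stash_setter) {
  if (policy == "error") {
    stop("no destination for populated slot ", slot, call. = FALSE)
  }
  if (policy == "warn_and_drop") {
    warning("dropping ", slot, " (no destination in target layout)",
            call. = FALSE)
    return(.report_drop(rep, slot, "no destination in target layout"))
  }
  warning(slot, " has no first-class destination; stashed under ",
          dest_desc, call. = FALSE)
  stash_setter()
  .report_stash(rep, slot, dest_desc)
}

#' Convert an AnnData container to a SingleCellExperiment
#'
#' Applies the Table-style default mapping (see [defaultMap()]): `X` and
#' `layers` become assays (transposed, features as rows), `obs`/`var`
#' become `colData`/`rowData`, `obsm` entries become `reducedDims`, `obsp`/
#' `varp` become `colPairs`/`rowPairs`, `uns` becomes `metadata`, and `raw`
#' becomes an alternative experiment named `"raw"`. A `varm` entry whose
#' key exactly matches an `obsm` key is attached to that reduced dimension
#' as feature loadings (`LinearEmbeddingMatrix`); unmatched `varm` entries
#' are stashed under `metadata[[".unmapped"]]` and recorded.
#'
#' @param ad An [AnnData()] container (backed handles are materialized).
#' @param map A [defaultMap()] `ConversionMap` for direction `"to_sce"`.
#' @param xAssayName Assay name given to `X`. Default `"X"`.
#' @return A [SingleCellExperiment::SingleCellExperiment] with a
#'   [lossReport()] attached.
#' @seealso [fromSCE()]
#' @export
toSCE <- function(ad, map = defaultMap("to_sce"), xAssayName = "X") {
  if (is(ad, "H5ADBacked")) ad <- toMemory(ad)
  validateAnnData(ad)
  stopifnot(map@direction == "to_sce")
  rep <- .empty_report()
  stash <- list()
  policy <- map@unmappedPolicy

  assays <- list()
  if (!is.null(adX(ad))) {
    dest <- .map_dest(map, "X")
    if (dest == "DROP") {
      rep <- .report_drop(rep, "X", "dropped by map")
    } else {
      assays[[xAssayName]] <- Matrix::t(adX(ad))
    }
  }
  for (k in names(adLayers(ad))) {
    dest <- .map_dest(map, "layers", k)
    nm <- if (dest %in% c("assays", "layers")) k else dest
    if (dest == "DROP") {
      rep <- .report_drop(rep, paste0("layers:", k), "dropped by map")
      next
    }
    if (nm != k) rep <- .report_rename(rep, paste0("layers:", k), nm)
    assays[[nm]] <- Matrix::t(adLayers(ad)[[k]])
  }
  if (anyDuplicated(names(assays))) {
    stop("assay name collision after mapping: ",
         paste(unique(names(assays)[duplicated(names(assays))]),
               collapse = ", "), call. = FALSE)
  }

  cd <- S4Vectors::DataFrame(adObs(ad)[, , drop = FALSE], check.names = FALSE)
  rownames(cd) <- obsNames(ad)
  rd <- S4Vectors::DataFrame(adVar(ad)[, , drop = FALSE], check.names = FALSE)
  rownames(rd) <- varNames(ad)

  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = assays, colData = cd, rowData = rd)

  # reducedDims from obsm (dataframe entries: numeric -> matrix, else stash)
  obsm_placed <- character(0)
  for (k in names(adObsm(ad))) {
    dest <- .map_dest(map, "obsm", k)
    if (dest == "DROP") {
      rep <- .report_drop(rep, paste0("obsm:", k), "dropped by map")
      next
    }
    nm <- if (dest == "reducedDims") k else dest
    v <- adObsm(ad)[[k]]
    if (is.data.frame(v)) {
      if (all(vapply(v, is.numeric, logical(1)))) {
        warning("coercing data.frame obsm[['", k, "']] to a matrix",
                call. = FALSE)
        v <- as.matrix(v)
        rownames(v) <- NULL
      } else {
        stash$obsm[[k]] <- v
        rep <- .report_stash(rep, paste0("obsm:", k),
                             paste0("metadata$", .STASH_KEY, "$obsm"))
        next
      }
    }
    if (nm != k) rep <- .report_rename(rep, paste0("obsm:", k), nm)
    SingleCellExperiment::reducedDim(sce, nm) <- v
    obsm_placed[k] <- nm
  }
  # varm: exact key match against placed obsm -> loadings of that reduction
  for (k in names(adVarm(ad))) {
    dest <- .map_dest(map, "varm", k)
    if (dest == "DROP") {
      rep <- .report_drop(rep, paste0("varm:", k), "dropped by map")
      next
    }
    v <- adVarm(ad)[[k]]
    if (dest == "reducedDims" && k %in% names(obsm_placed) &&
        !is.data.frame(v)) {
      nm <- obsm_placed[[k]]
      sf <- SingleCellExperiment::reducedDim(sce, nm, withDimnames = FALSE)
      SingleCellExperiment::reducedDim(sce, nm) <-
        SingleCellExperiment::LinearEmbeddingMatrix(
          sampleFactors = sf, featureLoadings = as.matrix(v))
    } else {
      rep <- .policy_unmapped(
        rep, policy, paste0("varm:", k),
        paste0("metadata$", .STASH_KEY, "$varm"),
        function() stash$varm[[k]] <<- v)
    }
  }

  pair_enc <- list()
  for (k in names(adObsp(ad))) {
    dest <- .map_dest(map, "obsp", k)
    if (dest == "DROP") {
      rep <- .report_drop(rep, paste0("obsp:", k), "dropped by map")
      next
    }
    nm <- if (dest == "colPairs") k else dest
    if (nm != k) rep <- .report_rename(rep, paste0("obsp:", k), nm)
    v <- adObsp(ad)[[k]]
    if (.pair_encoding_of(v) != "csc") {
      pair_enc$obsp[[nm]] <- .pair_encoding_of(v)
    }
    SingleCellExperiment::colPair(sce, nm) <- .as_pair_matrix(v)
  }
  for (k in names(adVarp(ad))) {
    dest <- .map_dest(map, "varp", k)
    if (dest == "DROP") {
      rep <- .report_drop(rep, paste0("varp:", k), "dropped by map")
      next
    }
    nm <- if (dest == "rowPairs") k else dest
    if (nm != k) rep <- .report_rename(rep, paste0("varp:", k), nm)
    v <- adVarp(ad)[[k]]
    if (.pair_encoding_of(v) != "csc") {
      pair_enc$varp[[nm]] <- .pair_encoding_of(v)
    }
    SingleCellExperiment::rowPair(sce, nm) <- .as_pair_matrix(v)
  }
  if (length(pair_enc) > 0L) stash$pair_encoding <- pair_enc

  if (length(adUns(ad)) > 0L && .map_dest(map, "uns") != "DROP") {
    S4Vectors::metadata(sce) <- adUns(ad)
  } else if (length(adUns(ad)) > 0L) {
    rep <- .report_drop(rep, "uns", "dropped by map")
  }

  if (!is.null(adRaw(ad))) {
    dest <- .map_dest(map, "raw")
    if (dest == "DROP") {
      rep <- .report_drop(rep, "raw", "dropped by map")
    } else {
      raw <- adRaw(ad)
      rrd <- S4Vectors::DataFrame(
        if (is.null(raw$var)) data.frame(matrix(nrow = ncol(raw$X),
                                                ncol = 0)) else raw$var,
        check.names = FALSE)
      if (!is.null(raw$varNames)) rownames(rrd) <- raw$varNames
      ae <- SummarizedExperiment::SummarizedExperiment(
        assays = list(X = Matrix::t(raw$X)), rowData = rrd)
      colnames(ae) <- obsNames(ad)
      if (!is.null(raw$varm)) S4Vectors::metadata(ae)$varm <- raw$varm
      SingleCellExperiment::altExp(sce, "raw") <- ae
    }
  }

  if (length(stash) > 0L) {
    md <- S4Vectors::metadata(sce)
    md[[.STASH_KEY]] <- stash
    S4Vectors::metadata(sce) <- md
  }
  .attach_report(sce, rep)
}

# pairwise matrices ride the pairs interface as sparse matrices
.as_pair_matrix <- function(m) {
  if (is(m, "sparseMatrix")) {
    as(as(m, "generalMatrix"), "CsparseMatrix")
  } else {
    as(Matrix::Matrix(as.matrix(m), sparse = TRUE), "CsparseMatrix")
  }
}

#' Convert a SingleCellExperiment to an AnnData container
#'
#' Inverse of [toSCE()] on its image: assays are transposed back (`X` from
#' `xAssay`, remaining assays into `layers`), `colData`/`rowData` become
#' `obs`/`var`, reduced dimensions become `obsm` (with feature loadings of
#' a `LinearEmbeddingMatrix` going to `varm` under the same key),
#' `colPairs`/`rowPairs` become `obsp`/`varp`, `metadata` becomes `uns`,
#' and the alternative experiment named `"raw"` becomes `raw`. Slots
#' stashed by [toSCE()] under `metadata[[".unmapped"]]` are recovered.
#' Alternative experiments with other names are ambiguous (they may be
#' paired measurements rather than an unfiltered matrix) and are dropped
#' with a warning and a report entry.
#'
#' @param sce A `SingleCellExperiment`.
#' @param map A `ConversionMap` for direction `"from_sce"`.
#' @param xAssay Name of the assay that becomes `X`; default `"X"` when
#'   present, else the first assay.
#' @return An [AnnData()] container with a [lossReport()] attached.
#' @export
fromSCE <- function(sce, map = defaultMap("from_sce"), xAssay = NULL) {
  rep <- .empty_report()
  an <- SummarizedExperiment::assayNames(sce)
  X <- NULL
  layers <- list()
  if (length(an) > 0L) {
    if (is.null(xAssay)) xAssay <- if ("X" %in% an) "X" else an[1]
    if (!xAssay %in% an) {
      stop("assay '", xAssay, "' not found; available: ",
           paste(an, collapse = ", "), call. = FALSE)
    }
    X <- Matrix::t(SummarizedExperiment::assay(sce, xAssay,
                                               withDimnames = FALSE))
    for (nm in setdiff(an, xAssay)) {
      layers[[nm]] <- Matrix::t(SummarizedExperiment::assay(
        sce, nm, withDimnames = FALSE))
    }
  }
  obs <- as.data.frame(SummarizedExperiment::colData(sce))
  obs_names <- colnames(sce)
  if (is.null(obs_names)) obs_names <- as.character(seq_len(ncol(sce)) - 1L)
  rownames(obs) <- NULL
  var <- as.data.frame(SummarizedExperiment::rowData(sce))
  var_names <- rownames(sce)
  if (is.null(var_names)) var_names <- as.character(seq_len(nrow(sce)) - 1L)
  rownames(var) <- NULL

  obsm <- list()
  varm <- list()
  for (nm in SingleCellExperiment::reducedDimNames(sce)) {
    v <- SingleCellExperiment::reducedDim(sce, nm, withDimnames = FALSE)
    if (is(v, "LinearEmbeddingMatrix")) {
      obsm[[nm]] <- .strip_dimnames(SingleCellExperiment::sampleFactors(v))
      varm[[nm]] <- .strip_dimnames(SingleCellExperiment::featureLoadings(v))
    } else {
      obsm[[nm]] <- v
    }
  }
  obsp <- list()
  for (nm in SingleCellExperiment::colPairNames(sce)) {
    obsp[[nm]] <- .strip_dimnames(
      SingleCellExperiment::colPair(sce, nm, asSparse = TRUE))
  }
  varp <- list()
  for (nm in SingleCellExperiment::rowPairNames(sce)) {
    varp[[nm]] <- .strip_dimnames(
      SingleCellExperiment::rowPair(sce, nm, asSparse = TRUE))
  }

  uns <- S4Vectors::metadata(sce)
  stash <- uns[[.STASH_KEY]]
  uns[[.STASH_KEY]] <- NULL
  if (!is.null(stash)) {
    for (k in names(stash$varm)) varm[[k]] <- stash$varm[[k]]
    for (k in names(stash$obsm)) obsm[[k]] <- stash$obsm[[k]]
    pe <- stash$pair_encoding
    for (k in names(pe$obsp)) {
      obsp[[k]] <- .restore_pair_encoding(obsp[[k]], pe$obsp[[k]])
    }
    for (k in names(pe$varp)) {
      varp[[k]] <- .restore_pair_encoding(varp[[k]], pe$varp[[k]])
    }
  }

  raw <- NULL
  for (ae_name in SingleCellExperiment::altExpNames(sce)) {
    if (ae_name == "raw") {
      ae <- SingleCellExperiment::altExp(sce, "raw", withDimnames = FALSE)
      raw <- list(
        X = Matrix::t(SummarizedExperiment::assay(ae, 1,
                                                  withDimnames = FALSE)),
        var = {
          v <- as.data.frame(SummarizedExperiment::rowData(ae))
          rownames(v) <- NULL
          v
        },
        varNames = rownames(SummarizedExperiment::rowData(ae)))
      vm <- S4Vectors::metadata(ae)$varm
      if (!is.null(vm)) raw$varm <- vm
    } else {
      warning("altExp '", ae_name, "' is ambiguous (raw vs paired ",
              "measurement); not converted", call. = FALSE)
      rep <- .report_drop(rep, paste0("altExp:", ae_name),
                          "ambiguous altExp; only 'raw' is mapped")
    }
  }

  ad <- AnnData(X = X, layers = layers, obs = obs, var = var,
                obsNames = obs_names, varNames = var_names,
                obsm = obsm, varm = varm, obsp = obsp, varp = varp,
                uns = uns, raw = raw)
  .attach_report(ad, rep)
}
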