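# AnnData <-> Seurat (v5 assay layout).
#
# Seurat is stricter than the H5AD format about names: cell and feature
# names must be unique and must not contain underscores, reduction keys
# must be alphanumeric with a trailing underscore. All repairs performed
# here are recorded in the LossReport so they can be audited; SCE targets
# never repair names (their ecosystem does not require it).

# make names legal for Seurat: underscores to dashes, then unique
.repair_names <- function(nms, rep, what) {
  fixed <- gsub("_", "-", nms, fixed = TRUE)
  fixed <- make.unique(fixed, sep = "-")
  changed <- which(fixed != nms)
  for (i in changed) {
    rep <- .report_rename(rep, paste0(what, ":", nms[i]), fixed[i])
  }
  list(names = fixed, report = rep)
}

# reduction key from an obsm key: strip the conventional "X_" prefix and
# anything that is not alphanumeric
.reduction_name <- function(key) {
  nm <- sub("^X_", "", key)
  gsub("[^[:alnum:]]", "", nm)
}

# X goes to the "counts" layer when integer-valued, otherwise "data"
.x_layer_name <- function(X) {
  vals <- if (is(X, "sparseMatrix")) X@x else as.vector(X)
  if (length(vals) == 0L ||
      all(is.finite(vals) & vals == round(vals))) "counts" else "data"
}

#' Convert an AnnData container to a Seurat object
#'
#' `X` and `layers` become layers of a single v5 assay (transposed,
#' features as rows) -- `X` lands in `"counts"` when it is integer-valued
#' and `"data"` otherwise (overridable via `xLayerName`). `obs` becomes
#' cell-level metadata, `var` assay-level metadata, `obsm` entries become
#' reductions (keys normalized by stripping the conventional `"X_"`
#' prefix; recorded as renames), a `varm` entry whose key matches a
#' reduction attaches as its feature loadings, `obsp` entries become
#' graphs and `uns` goes to `misc`. Seurat has no slot for `varp` or for
#' `raw`: both are stashed under `Misc(object)[[".unmapped"]]` with a
#' warning and a report entry, and are recovered by [fromSeurat()].
#'
#' Cell and feature names are repaired to Seurat's rules (no underscores,
#' unique); every repair is recorded in the [lossReport()].
#'
#' @param ad An [AnnData()] container with at least one variable.
#' @param map A `ConversionMap` for direction `"to_seurat"`.
#' @param assayName Name of the created assay. Default `"RNA"`.
#' @param xLayerName Layer receiving `X`; default per the integer rule.
#' @return A `Seurat` object with a [lossReport()] attached.
#' @export
toSeurat <- function(ad, map = defaultMap("to_seurat"), assayName = "RNA",
                     xLayerName = NULL) {
  if (is(ad, "H5ADBacked")) ad <- toMemory(ad)
  validateAnnData(ad)
  stopifnot(map@direction == "to_seurat")
  if (nVar(ad) == 0L) {
    stop("cannot build a Seurat object with 0 features", call. = FALSE)
  }
  rep <- .empty_report()
  policy <- map@unmappedPolicy
  stash <- list()

  r <- .repair_names(obsNames(ad), rep, "cell")
  cells <- r$names; rep <- r$report
  r <- .repair_names(varNames(ad), rep, "feature")
  feats <- r$names; rep <- r$report

  t_for_seurat <- function(m) {
    m <- Matrix::t(m)
    if (is(m, "sparseMatrix")) {
      m <- as(as(m, "generalMatrix"), "CsparseMatrix")
    } else {
      m <- as.matrix(m)
    }
    dimnames(m) <- list(feats, cells)
    m
  }

  # Seurat stores layers column-sparse (or coerces dense input); record the
  # source representation so the inverse conversion restores it exactly
  layer_data <- list()
  if (!is.null(adX(ad)) && .map_dest(map, "X") != "DROP") {
    if (is.null(xLayerName)) xLayerName <- .x_layer_name(adX(ad))
    layer_data[[xLayerName]] <- t_for_seurat(adX(ad))
    if (.pair_encoding_of(adX(ad)) != "csc") {
      stash$layer_encoding[[xLayerName]] <- .pair_encoding_of(adX(ad))
    }
  } else if (!is.null(adX(ad))) {
    rep <- .report_drop(rep, "X", "dropped by map")
  }
  for (k in names(adLayers(ad))) {
    dest <- .map_dest(map, "layers", k)
    if (dest == "DROP") {
      rep <- .report_drop(rep, paste0("layers:", k), "dropped by map")
      next
    }
    nm <- if (dest %in% c("layers", "assays")) k else dest
    if (nm != k) rep <- .report_rename(rep, paste0("layers:", k), nm)
    if (nm %in% names(layer_data)) {
      stop("layer name collision after mapping: ", nm, call. = FALSE)
    }
    layer_data[[nm]] <- t_for_seurat(adLayers(ad)[[k]])
    if (.pair_encoding_of(adLayers(ad)[[k]]) != "csc") {
      stash$layer_encoding[[nm]] <- .pair_encoding_of(adLayers(ad)[[k]])
    }
  }
  if (length(layer_data) == 0L) {
    # Seurat requires at least one layer; provide an all-zero counts layer
    # and mark it so the inverse conversion removes it again
    layer_data$counts <- Matrix::sparseMatrix(
      i = integer(0), j = integer(0), x = numeric(0),
      dims = c(nVar(ad), nObs(ad)), dimnames = list(feats, cells))
    stash$placeholder_layer <- "counts"
  }

  # CreateAssay5Object only accepts counts/data; build the assay from the
  # first layer under the matching slot, then rename if needed
  first <- names(layer_data)[1]
  assay <- if (first == "counts") {
    SeuratObject::CreateAssay5Object(counts = layer_data[[1]])
  } else {
    SeuratObject::CreateAssay5Object(data = layer_data[[1]])
  }
  if (!first %in% c("counts", "data")) {
    SeuratObject::LayerData(assay, first) <- layer_data[[1]]
    SeuratObject::LayerData(assay, "data") <- NULL
  }
  for (nm in names(layer_data)[-1]) {
    SeuratObject::LayerData(assay, nm) <- layer_data[[nm]]
  }

  meta <- NULL
  if (ncol(adObs(ad)) > 0L) {
    meta <- adObs(ad)
    rownames(meta) <- cells
  }
  obj <- SeuratObject::CreateSeuratObject(assay, assay = assayName,
                                          meta.data = meta,
                                          project = "AnnData")
  if (ncol(adVar(ad)) > 0L) {
    vmeta <- adVar(ad)
    rownames(vmeta) <- feats
    obj[[assayName]][[colnames(vmeta)]] <- vmeta
  }

  # reductions from obsm; matching varm keys become loadings
  placed <- character(0)   # normalized reduction name -> original obsm key
  for (k in names(adObsm(ad))) {
    dest <- .map_dest(map, "obsm", k)
    if (dest == "DROP") {
      rep <- .report_drop(rep, paste0("obsm:", k), "dropped by map")
      next
    }
    nm <- if (dest == "reductions") .reduction_name(k) else dest
    v <- adObsm(ad)[[k]]
    if (is.data.frame(v)) {
      if (all(vapply(v, is.numeric, logical(1)))) {
        warning("coercing data.frame obsm[['", k, "']] to a matrix",
                call. = FALSE)
        v <- as.matrix(v)
      } else {
        stash$obsm[[k]] <- v
        rep <- .report_stash(rep, paste0("obsm:", k),
                             paste0("misc$", .STASH_KEY, "$obsm"))
        next
      }
    }
    if (ncol(v) == 0L) {
      # a reduction needs at least one dimension; keep the entry in the
      # stash so nothing is lost
      stash$obsm[[k]] <- v
      rep <- .report_stash(rep, paste0("obsm:", k),
                           paste0("misc$", .STASH_KEY, "$obsm"))
      next
    }
    if (nm != k) rep <- .report_rename(rep, paste0("obsm:", k), nm)
    key <- paste0(nm, "_")
    emb <- as.matrix(v)
    rownames(emb) <- cells
    colnames(emb) <- paste0(key, seq_len(ncol(emb)))
    dr <- SeuratObject::CreateDimReducObject(
      embeddings = emb, key = key, assay = assayName,
      misc = list(obsm_key = k))
    obj[[nm]] <- dr
    placed[nm] <- k
  }
  for (k in names(adVarm(ad))) {
    dest <- .map_dest(map, "varm", k)
    if (dest == "DROP") {
      rep <- .report_drop(rep, paste0("varm:", k), "dropped by map")
      next
    }
    nm <- .reduction_name(k)
    v <- adVarm(ad)[[k]]
    if (dest == "reductions" && nm %in% names(placed) && !is.data.frame(v)) {
      dr <- obj[[nm]]
      ld <- as.matrix(v)
      rownames(ld) <- feats
      colnames(ld) <- paste0(SeuratObject::Key(dr), seq_len(ncol(ld)))
      SeuratObject::Loadings(dr, projected = FALSE) <- ld
      SeuratObject::Misc(dr, "varm_key") <- k
      obj[[nm]] <- dr
    } else {
      rep <- .policy_unmapped(
        rep, policy, paste0("varm:", k),
        paste0("misc$", .STASH_KEY, "$varm"),
        function() stash$varm[[k]] <<- v)
    }
  }

  for (k in names(adObsp(ad))) {
    dest <- .map_dest(map, "obsp", k)
    if (dest == "DROP") {
      rep <- .report_drop(rep, paste0("obsp:", k), "dropped by map")
      next
    }
    nm <- if (dest == "graphs") k else dest
    if (nm != k) rep <- .report_rename(rep, paste0("obsp:", k), nm)
    v <- adObsp(ad)[[k]]
    if (.pair_encoding_of(v) != "csc") {
      stash$pair_encoding$obsp[[nm]] <- .pair_encoding_of(v)
    }
    g <- .as_pair_matrix(v)
    dimnames(g) <- list(cells, cells)
    g <- SeuratObject::as.Graph(g)
    SeuratObject::DefaultAssay(g) <- assayName
    obj[[nm]] <- g
  }

  for (k in names(adVarp(ad))) {
    rep <- .policy_unmapped(
      rep, policy, paste0("varp:", k),
      paste0("misc$", .STASH_KEY, "$varp"),
      local({ kk <- k; function() stash$varp[[kk]] <<- adVarp(ad)[[kk]] }))
  }

  if (!is.null(adRaw(ad))) {
    rep <- .policy_unmapped(
      rep, policy, "raw", paste0("misc$", .STASH_KEY, "$raw"),
      function() stash$raw <<- adRaw(ad))
  }

  # record which layer carries X (NA when the container had no X), so the
  # inverse conversion restores the exact X/layers split
  stash$x_layer <- if (!is.null(adX(ad)) && .map_dest(map, "X") != "DROP") {
    xLayerName
  } else {
    NA_character_
  }

  misc <- list()
  if (length(adUns(ad)) > 0L && .map_dest(map, "uns") != "DROP") {
    misc <- adUns(ad)
  } else if (length(adUns(ad)) > 0L) {
    rep <- .report_drop(rep, "uns", "dropped by map")
  }
  if (length(stash) > 0L) misc[[.STASH_KEY]] <- stash
  for (k in names(misc)) SeuratObject::Misc(obj, k) <- misc[[k]]

  .attach_report(obj, rep)
}

#' Convert a Seurat object to an AnnData container
#'
#' Inverse of [toSeurat()] on its image. The assay's layers are transposed
#' back: the layer named `"counts"` (else `"data"`, else the first layer,
#' or an explicit `xLayer`) becomes `X` and the rest become `layers`.
#' Cell metadata becomes `obs` (minus the columns `CreateSeuratObject`
#' adds automatically, unless `keepSeuratColumns = TRUE`), assay metadata
#' becomes `var`, reductions become `obsm` entries (original key restored
#' from the reduction's misc when [toSeurat()] recorded one, else
#' `"X_<name>"`), loadings become `varm`, graphs become `obsp`, and misc
#' becomes `uns`. Slots stashed under `Misc(object)[[".unmapped"]]`
#' (`varp`, `raw`, mixed-type `obsm`) are restored to their original
#' slots.
#'
#' @param obj A `Seurat` object with a single assay (multiple assays are
#'   ambiguous because AnnData is single-modality: pick one via `assay`).
#' @param map A `ConversionMap` for direction `"from_seurat"`.
#' @param assay Assay to convert when the object has several.
#' @param xLayer Layer that becomes `X`.
#' @param keepSeuratColumns Keep `orig.ident`/`nCount_*`/`nFeature_*`
#'   metadata columns. Default `FALSE`.
#' @return An [AnnData()] container with a [lossReport()] attached.
#' @export
fromSeurat <- function(obj, map = defaultMap("from_seurat"), assay = NULL,
                       xLayer = NULL, keepSeuratColumns = FALSE) {
  rep <- .empty_report()
  assays <- SeuratObject::Assays(obj)
  if (is.null(assay)) {
    if (length(assays) > 1L) {
      stop("object has multiple assays (", paste(assays, collapse = ", "),
           "); AnnData is single-modality, pick one with `assay`",
           call. = FALSE)
    }
    assay <- assays[1]
  }
  a5 <- obj[[assay]]
  layer_names <- SeuratObject::Layers(a5)
  placeholder <- SeuratObject::Misc(obj)[[.STASH_KEY]]$placeholder_layer
  if (!is.null(placeholder)) {
    layer_names <- setdiff(layer_names, placeholder)
  }
  marker <- SeuratObject::Misc(obj)[[.STASH_KEY]]$x_layer
  if (is.null(xLayer)) {
    xLayer <- if (!is.null(marker)) {
      marker   # NA when the source container had no X
    } else if ("counts" %in% layer_names) {
      "counts"
    } else if ("data" %in% layer_names) {
      "data"
    } else {
      layer_names[1]
    }
  }
  layer_enc <- SeuratObject::Misc(obj)[[.STASH_KEY]]$layer_encoding
  back <- function(nm) {
    m <- .strip_dimnames(Matrix::t(SeuratObject::LayerData(a5, nm)))
    .restore_pair_encoding(m, layer_enc[[nm]])
  }
  X <- if (length(layer_names) > 0L && !is.na(xLayer)) back(xLayer)
  layers <- list()
  for (nm in setdiff(layer_names, if (is.na(xLayer)) character(0) else xLayer)) {
    layers[[nm]] <- back(nm)
  }

  obs <- obj@meta.data
  obs_names <- rownames(obs)
  if (!keepSeuratColumns) {
    auto <- c("orig.ident", paste0("nCount_", assay),
              paste0("nFeature_", assay))
    obs <- obs[, setdiff(colnames(obs), auto), drop = FALSE]
  }
  rownames(obs) <- NULL
  var <- a5[[]]
  var_names <- rownames(var)
  if (is.null(var_names)) var_names <- rownames(a5)
  var <- as.data.frame(var)
  rownames(var) <- NULL

  obsm <- list()
  varm <- list()
  for (nm in SeuratObject::Reductions(obj)) {
    dr <- obj[[nm]]
    key <- SeuratObject::Misc(dr, "obsm_key")
    if (is.null(key)) key <- paste0("X_", nm)
    emb <- SeuratObject::Embeddings(dr)
    obsm[[key]] <- .strip_dimnames(unname(emb))
    ld <- SeuratObject::Loadings(dr)
    if (!is.null(ld) && length(ld) > 0L) {
      vkey <- SeuratObject::Misc(dr, "varm_key")
      if (is.null(vkey)) vkey <- key
      varm[[vkey]] <- .strip_dimnames(unname(ld))
    }
  }
  obsp <- list()
  for (nm in SeuratObject::Graphs(obj)) {
    g <- obj[[nm]]
    obsp[[nm]] <- .strip_dimnames(as(as(g, "CsparseMatrix"), "generalMatrix"))
  }

  uns <- as.list(SeuratObject::Misc(obj))
  stash <- uns[[.STASH_KEY]]
  uns[[.STASH_KEY]] <- NULL
  varp <- list()
  raw <- NULL
  if (!is.null(stash)) {
    for (k in names(stash$varp)) varp[[k]] <- stash$varp[[k]]
    for (k in names(stash$varm)) varm[[k]] <- stash$varm[[k]]
    for (k in names(stash$obsm)) obsm[[k]] <- stash$obsm[[k]]
    if (!is.null(stash$raw)) raw <- stash$raw
    pe <- stash$pair_encoding
    for (k in names(pe$obsp)) {
      obsp[[k]] <- .restore_pair_encoding(obsp[[k]], pe$obsp[[k]])
    }
  }

  ad <- AnnData(X = X, layers = layers, obs = obs, var = var,
                obsNames = obs_names, varNames = var_names,
                obsm = obsm, varm = varm, obsp = obsp, varp = varp,
                uns = uns, raw = raw)
  .attach_report(ad, rep)
}
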