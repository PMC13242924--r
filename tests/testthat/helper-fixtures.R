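suppressPackageStartupMessages({
  library(Matrix)
})

# ---- deep equality across containers --------------------------------------

AD_SLOTS <- c("adX", "adObs", "adVar", "adLayers", "adObsm", "adVarm",
              "adObsp", "adVarp", "adUns")

# order-insensitive comparison for mapping-like lists (HDF5 group iteration
# order is not semantic)
sort_maps <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    nm <- names(x)
    if (!is.null(nm) && length(x) > 1L) x <- x[order(nm, method = "radix")]
    lapply(x, sort_maps)
  } else {
    x
  }
}

ad_slot_diffs <- function(a, b) {
  msgs <- character(0)
  for (s in AD_SLOTS) {
    va <- sort_maps(get(s)(a))
    vb <- sort_maps(get(s)(b))
    if (!isTRUE(all.equal(va, vb))) {
      msgs <- c(msgs, paste0(s, ": ",
                             paste(all.equal(va, vb), collapse = "; ")))
    }
  }
  if (!identical(obsNames(a), obsNames(b))) msgs <- c(msgs, "obsNames")
  if (!identical(varNames(a), varNames(b))) msgs <- c(msgs, "varNames")
  ra <- adRaw(a)
  rb <- adRaw(b)
  if (is.null(ra) != is.null(rb)) {
    msgs <- c(msgs, "raw presence")
  } else if (!is.null(ra)) {
    for (f in names(ra)) {
      if (!isTRUE(all.equal(ra[[f]], rb[[f]]))) {
        msgs <- c(msgs, paste0("raw$", f))
      }
    }
  }
  msgs
}

expect_ad_equal <- function(a, b, info = NULL) {
  msgs <- ad_slot_diffs(a, b)
  expect(length(msgs) == 0L,
         paste0("containers differ", if (!is.null(info)) paste0(" [", info,
                "]"), ": ", paste(msgs, collapse = " | ")))
  invisible(a)
}

# ---- shared fixture corpus (generated once per test run) -------------------

.test_cache <- new.env(parent = emptyenv())

corpus_dir <- function() {
  if (is.null(.test_cache$dir)) {
    dir <- file.path(tempdir(), "h5adkit-corpus")
    .test_cache$paths <- suppressWarnings(writeFixtureCorpus(dir))
    .test_cache$dir <- dir
  }
  .test_cache$dir
}

corpus_files <- function() {
  corpus_dir()
  .test_cache$paths
}

corpus_container <- function(name) {
  generateFixture(fixtureCorpus()[[name]])
}

# a rich container exercising every slot at small size
full_fixture <- function(seed = 42L, nObs = 12L, nVar = 7L) {
  generateFixture(fixtureSpec(
    nObs, nVar, seed = seed,
    features = c("sparse_csr_X", "layers", "raw", "categoricals",
                 "nullable_cols", "nested_uns", "obsm_varm_pair",
                 "obsp", "varp", "missing_values")))
}

# ---- file corruption helpers (planted defects) -----------------------------

with_h5_handle <- function(path, fn) {
  h5 <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(h5))
  fn(h5)
}

copy_and_corrupt <- function(src, fn) {
  dst <- tempfile(fileext = ".h5ad")
  file.copy(src, dst)
  with_h5_handle(dst, fn)
  dst
}

rewrite_attr <- function(h5, path, name, value) {
  oid <- rhdf5::H5Oopen(h5, path)
  on.exit(rhdf5::H5Oclose(oid))
  if (rhdf5::H5Aexists(oid, name)) rhdf5::H5Adelete(oid, name)
  rhdf5::h5writeAttribute(value, oid, name, variableLengthString = TRUE,
                          asScalar = length(value) == 1L, encoding = "UTF-8")
}

# replace a 1-d integer dataset, keeping its encoding attributes
rewrite_int_dataset <- function(h5, path, values, dtype = "integer",
                                enc = "array") {
  rhdf5::h5delete(h5, path)
  h5adkit:::.h5_write_dataset(h5, path, values, dtype)
  if (!is.null(enc)) h5adkit:::.write_encoding_attrs(h5, path, enc)
}

rewrite_bool_dataset <- function(h5, path, values) {
  rhdf5::h5delete(h5, path)
  h5adkit:::.h5_write_dataset(h5, path, values, "bool")
  h5adkit:::.write_encoding_attrs(h5, path, "array")
}

delete_attr <- function(h5, path, name) {
  oid <- rhdf5::H5Oopen(h5, path)
  on.exit(rhdf5::H5Oclose(oid))
  if (rhdf5::H5Aexists(oid, name)) rhdf5::H5Adelete(oid, name)
}

# ---- conversion accounting -------------------------------------------------

# populated optional source entries, counted at key level for keyed slots
populated_entries <- function(ad) {
  n <- 0L
  if (!is.null(adX(ad))) n <- n + 1L
  n <- n + length(adLayers(ad)) + length(adObsm(ad)) + length(adVarm(ad)) +
    length(adObsp(ad)) + length(adVarp(ad))
  if (length(adUns(ad)) > 0L) n <- n + 1L
  if (!is.null(adRaw(ad))) n <- n + 1L
  n
}

placed_entries_sce <- function(sce) {
  n <- length(SummarizedExperiment::assayNames(sce))
  for (nm in SingleCellExperiment::reducedDimNames(sce)) {
    v <- SingleCellExperiment::reducedDim(sce, nm, withDimnames = FALSE)
    n <- n + if (is(v, "LinearEmbeddingMatrix")) 2L else 1L
  }
  n <- n + length(SingleCellExperiment::colPairNames(sce)) +
    length(SingleCellExperiment::rowPairNames(sce))
  md <- S4Vectors::metadata(sce)
  md[[".unmapped"]] <- NULL
  if (length(md) > 0L) n <- n + 1L
  if ("raw" %in% SingleCellExperiment::altExpNames(sce)) n <- n + 1L
  n
}

placed_entries_seurat <- function(so, ad, assay = "RNA") {
  stash <- SeuratObject::Misc(so)[[".unmapped"]]
  layers <- SeuratObject::Layers(so[[assay]])
  if (!is.null(stash$placeholder_layer)) {
    layers <- setdiff(layers, stash$placeholder_layer)
  }
  n <- length(layers)
  for (nm in SeuratObject::Reductions(so)) {
    ld <- SeuratObject::Loadings(so[[nm]])
    n <- n + if (length(ld) > 0L) 2L else 1L
  }
  n <- n + length(SeuratObject::Graphs(so))
  misc <- SeuratObject::Misc(so)
  misc[[".unmapped"]] <- NULL
  if (length(misc) > 0L) n <- n + 1L
  n
}
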