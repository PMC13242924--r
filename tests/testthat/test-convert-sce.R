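# AnnData <-> SingleCellExperiment conversion.

suppressPackageStartupMessages({
  library(SingleCellExperiment)
})

test_that("every assay is the exact transpose of its source matrix", {
  ad <- full_fixture()
  sce <- suppressWarnings(toSCE(ad))
  expect_identical(dim(sce), c(nVar(ad), nObs(ad)))
  Xa <- as.matrix(adX(ad))
  Xs <- as.matrix(assay(sce, "X", withDimnames = FALSE))
  for (i in seq_len(nrow(Xa))) {
    expect_identical(unname(Xa[i, ]), unname(Xs[, i]))
  }
  for (nm in names(adLayers(ad))) {
    expect_identical(unname(as.matrix(assay(sce, nm, withDimnames = FALSE))),
                     unname(t(as.matrix(adLayers(ad)[[nm]]))), info = nm)
  }
})

test_that("obs/var map to colData/rowData with names and factor levels", {
  ad <- corpus_container("categoricals")
  sce <- toSCE(ad)
  expect_identical(colnames(sce), obsNames(ad))
  expect_identical(rownames(sce), varNames(ad))
  expect_identical(as.character(colData(sce)$celltype),
                   as.character(adObs(ad)$celltype))
  expect_true(is.ordered(colData(sce)$grade))
  expect_identical(levels(colData(sce)$grade), c("low", "mid", "high"))
})

test_that("a container with only obs/var converts to an assay-less SCE", {
  ad <- AnnData(obs = data.frame(a = 1:3), var = data.frame(b = 1:2))
  sce <- toSCE(ad)
  expect_identical(length(assayNames(sce)), 0L)
  expect_identical(dim(colData(sce)), c(3L, 1L))
  expect_identical(dim(rowData(sce)), c(2L, 1L))
})

test_that("matching obsm/varm keys attach as loadings, others are stashed", {
  ad <- corpus_container("obsm_varm")   # has pca/pca pair + unmatched keys
  sce <- suppressWarnings(toSCE(ad))
  expect_s4_class(reducedDim(sce, "pca"), "LinearEmbeddingMatrix")
  expect_identical(
    unname(sampleFactors(reducedDim(sce, "pca", withDimnames = FALSE))),
    unname(adObsm(ad)$pca))
  expect_identical(
    unname(featureLoadings(reducedDim(sce, "pca", withDimnames = FALSE))),
    unname(adVarm(ad)$pca))
  # unmatched varm went to the documented stash and into the report
  rep <- lossReport(sce)
  expect_true("varm:dispersions" %in% reportStashed(rep)$slot)
  expect_true(!is.null(metadata(sce)[[".unmapped"]]$varm$dispersions))
})

test_that("pairwise slots ride colPairs/rowPairs with identical matrices", {
  ad <- corpus_container("pairwise")
  sce <- toSCE(ad)
  expect_setequal(colPairNames(sce), names(adObsp(ad)))
  expect_setequal(rowPairNames(sce), names(adVarp(ad)))
  got <- colPair(sce, "knn", asSparse = TRUE)
  expect_identical(unname(as.matrix(got)),
                   unname(as.matrix(adObsp(ad)$knn)))
})

test_that("raw becomes an altExp carrying the transposed matrix and var", {
  ad <- corpus_container("raw")
  sce <- toSCE(ad)
  expect_true("raw" %in% altExpNames(sce))
  ae <- altExp(sce, "raw", withDimnames = FALSE)
  expect_identical(unname(as.matrix(assay(ae, 1, withDimnames = FALSE))),
                   unname(t(as.matrix(adRaw(ad)$X))))
  expect_identical(rowData(ae)$retained, adRaw(ad)$var$retained)
})

test_that("SCE round-trip is identity on every mapped slot", {
  for (nm in c("minimal", "dense_x", "csr_x", "csc_x", "layers",
               "categoricals", "nullable", "pairwise", "obsm_varm",
               "raw", "missing_values", "everything")) {
    ad <- corpus_container(nm)
    back <- suppressWarnings(fromSCE(suppressWarnings(toSCE(ad))))
    expect_ad_equal(ad, back, info = nm)
  }
})

test_that("the conservation equation holds for every corpus conversion", {
  for (nm in names(fixtureCorpus())) {
    ad <- corpus_container(nm)
    sce <- suppressWarnings(toSCE(ad))
    rep <- lossReport(sce)
    expect_identical(
      placed_entries_sce(sce) + nrow(reportDropped(rep)) +
        nrow(reportStashed(rep)),
      populated_entries(ad), info = nm)
  }
})

test_that("x assay selection is honoured when converting back", {
  ad <- corpus_container("layers")
  sce <- toSCE(ad, xAssayName = "counts_x")
  expect_true("counts_x" %in% assayNames(sce))
  back <- fromSCE(sce, xAssay = "counts_x")
  expect_identical(unname(as.matrix(adX(back))),
                   unname(as.matrix(adX(ad))))
  expect_setequal(names(adLayers(back)), names(adLayers(ad)))
  expect_error(fromSCE(sce, xAssay = "nope"), "not found")
})

test_that("user map overrides rename and drop slots", {
  ad <- corpus_container("obsm_varm")
  map <- defaultMap("to_sce", overrides = c("obsm:X_umap" = "umap_custom",
                                            "varp" = "DROP"))
  sce <- suppressWarnings(toSCE(ad, map = map))
  expect_true("umap_custom" %in% reducedDimNames(sce))
  expect_false("X_umap" %in% reducedDimNames(sce))
  rep <- lossReport(sce)
  expect_true(any(reportRenamed(rep)$old == "obsm:X_umap" &
                    reportRenamed(rep)$new == "umap_custom"))
  expect_error(defaultMap("to_sce", overrides = c(bogus = "assays")),
               "unknown slot")
})

test_that("non-raw altExps are surfaced as ambiguous, not converted", {
  ad <- AnnData(X = matrix(0, 3, 2))
  sce <- toSCE(ad)
  suppressWarnings(
    SingleCellExperiment::altExp(sce, "adt") <-
      SummarizedExperiment::SummarizedExperiment(
        assays = list(m = matrix(0, 4, 3))))
  expect_warning(back <- fromSCE(sce), "ambiguous")
  expect_null(adRaw(back))
  expect_true(any(grepl("altExp:adt", reportDropped(lossReport(back))$slot)))
})
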