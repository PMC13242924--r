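# AnnData <-> Seurat (v5 layout) conversion.

suppressPackageStartupMessages({
  library(SeuratObject)
})

to_seurat_quiet <- function(ad, ...) suppressWarnings(toSeurat(ad, ...))

test_that("layers are exact transposes and X follows the integer rule", {
  ad <- corpus_container("layers")   # integer-valued dense X
  so <- to_seurat_quiet(ad)
  expect_true("counts" %in% Layers(so[["RNA"]]))   # X is integer-valued
  m <- as.matrix(LayerData(so[["RNA"]], "counts"))
  Xa <- as.matrix(adX(ad))
  for (i in seq_len(nrow(Xa))) {
    expect_identical(unname(as.numeric(Xa[i, ])), unname(m[, i]))
  }
  # a real-valued X lands in "data" instead
  ad2 <- AnnData(X = matrix(rnorm(6), 2, 3))
  so2 <- to_seurat_quiet(ad2)
  expect_true("data" %in% Layers(so2[["RNA"]]))
  expect_false("counts" %in% Layers(so2[["RNA"]]))
})

test_that("obs and var map to cell- and assay-level metadata", {
  ad <- corpus_container("categoricals")
  so <- to_seurat_quiet(ad)
  expect_identical(as.character(so@meta.data$celltype),
                   as.character(adObs(ad)$celltype))
  av <- so[["RNA"]][[]]
  expect_identical(av$highly_variable, adVar(ad)$highly_variable)
})

test_that("obsp entries become graphs with identical structure", {
  ad <- corpus_container("pairwise")
  so <- to_seurat_quiet(ad)
  expect_setequal(Graphs(so), names(adObsp(ad)))
  g <- so[["knn"]]
  expect_identical(unname(as.matrix(g)),
                   unname(as.matrix(adObsp(ad)$knn)))
})

test_that("uns content lands in misc, deep-equal", {
  ad <- corpus_container("nested_uns")
  so <- to_seurat_quiet(ad)
  for (k in names(adUns(ad))) {
    expect_identical(Misc(so, k), adUns(ad)[[k]], info = k)
  }
})

test_that("varp has no first-class slot: stashed, reported, warned", {
  ad <- corpus_container("pairwise")
  w <- capture_warnings(so <- toSeurat(ad))
  expect_true(any(grepl("varp", w)))
  rep <- lossReport(so)
  expect_true(all(paste0("varp:", names(adVarp(ad))) %in%
                    reportStashed(rep)$slot))
  stash <- Misc(so)[[".unmapped"]]
  expect_setequal(names(stash$varp), names(adVarp(ad)))
  # absent from every first-class slot
  expect_false(any(names(adVarp(ad)) %in% Graphs(so)))
})

test_that("obsm keys are normalized to reduction names and recorded", {
  ad <- corpus_container("obsm_varm")
  so <- to_seurat_quiet(ad)
  expect_true(all(c("pca", "umap") %in% Reductions(so)))
  rep <- lossReport(so)
  expect_true(any(reportRenamed(rep)$old == "obsm:X_umap" &
                    reportRenamed(rep)$new == "umap"))
  # matching varm attaches as loadings of the same-named reduction
  ld <- Loadings(so[["pca"]])
  expect_identical(unname(ld), unname(adVarm(ad)$pca))
})

test_that("Seurat round-trip is identity on mapped slots and stashes", {
  for (nm in c("dense_x", "csr_x", "csc_x", "layers", "categoricals",
               "nullable", "pairwise", "obsm_varm", "raw",
               "missing_values", "everything")) {
    ad <- corpus_container(nm)
    back <- suppressWarnings(fromSeurat(to_seurat_quiet(ad)))
    expect_ad_equal(ad, back, info = nm)
  }
})

test_that("the conservation equation holds for Seurat conversions", {
  for (nm in c("dense_x", "layers", "pairwise", "obsm_varm", "raw",
               "everything")) {
    ad <- corpus_container(nm)
    so <- to_seurat_quiet(ad)
    rep <- lossReport(so)
    expect_identical(
      placed_entries_seurat(so, ad) + nrow(reportDropped(rep)) +
        nrow(reportStashed(rep)),
      populated_entries(ad), info = nm)
  }
})

test_that("illegal cell/feature names are repaired and recorded", {
  ad <- AnnData(X = matrix(1:6, 2, 3),
                obsNames = c("cell_1", "cell_1"),
                varNames = c("gene_a", "gene-b", "gene_a"))
  so <- to_seurat_quiet(ad)
  expect_false(any(grepl("_", colnames(so))))
  expect_false(anyDuplicated(colnames(so)) > 0)
  expect_false(anyDuplicated(rownames(so)) > 0)
  rep <- lossReport(so)
  expect_true(any(grepl("^cell:cell_1", reportRenamed(rep)$old)))
  expect_true(any(grepl("^feature:gene_a", reportRenamed(rep)$old)))
})

test_that("a zero-feature container cannot become a Seurat object", {
  ad <- AnnData(obs = data.frame(a = 1:3))
  expect_error(toSeurat(ad), "0 features")
})

test_that("multiple assays require an explicit choice", {
  ad <- corpus_container("dense_x")
  so <- to_seurat_quiet(ad)
  # graft a second assay
  m <- as(Matrix::rsparsematrix(4, nObs(ad), 0.5), "CsparseMatrix")
  m@x <- abs(m@x)
  dimnames(m) <- list(paste0("adt", 1:4), colnames(so))
  so[["ADT"]] <- suppressWarnings(CreateAssay5Object(counts = m))
  err <- tryCatch(fromSeurat(so), error = identity)
  expect_match(conditionMessage(err), "RNA")
  expect_match(conditionMessage(err), "ADT")
  back <- suppressWarnings(fromSeurat(so, assay = "RNA"))
  expect_identical(unname(as.matrix(adX(back))),
                   unname(as.matrix(adX(ad))))
})

test_that("a container with layers but no X keeps that split", {
  ad <- AnnData(layers = list(norm = matrix(rnorm(6), 2, 3)),
                obsNames = c("c1", "c2"), varNames = c("g1", "g2", "g3"))
  so <- to_seurat_quiet(ad)
  back <- suppressWarnings(fromSeurat(so))
  expect_null(adX(back))
  expect_identical(names(adLayers(back)), "norm")
  expect_identical(adLayers(back)$norm, adLayers(ad)$norm)
})
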