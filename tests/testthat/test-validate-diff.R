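# Conformance validator and semantic diff.

base_file <- function() corpus_files()[["everything"]]

test_that("every corpus-written file is conformant", {
  for (f in corpus_files()) {
    rep <- validateH5AD(f)
    expect_true(isConformant(rep), info = basename(f))
  }
})

test_that("each planted defect kind is flagged at its path", {
  f <- base_file()
  cases <- list(
    list(rule = "enc/unknown-type", path = "/X",
         fn = function(h5) rewrite_attr(h5, "X", "encoding-type", "bogus")),
    list(rule = "sparse/indptr-length", path = "/X",
         fn = function(h5) {
           ip <- as.integer(rhdf5::h5read(h5, "X/indptr"))
           rewrite_int_dataset(h5, "X/indptr", ip[-length(ip)], "int64",
                               enc = NULL)
         }),
    list(rule = "categorical/code-range", path = "/obs/celltype",
         fn = function(h5) {
           cd <- as.integer(rhdf5::h5read(h5, "obs/celltype/codes"))
           cd[1] <- 99L
           rewrite_int_dataset(h5, "obs/celltype/codes", cd)
         }),
    list(rule = "dataframe/column-length", path = "/obs/n_genes",
         fn = function(h5) {
           x <- as.integer(rhdf5::h5read(h5, "obs/n_genes"))
           rewrite_int_dataset(h5, "obs/n_genes", x[-1])
         }),
    list(rule = "sparse/shape-missing", path = "/obsp/knn",
         fn = function(h5) delete_attr(h5, "obsp/knn", "shape")),
    list(rule = "nullable/length-mismatch", path = "/obs/n_umi",
         fn = function(h5) {
           m <- h5adkit:::.h5_read_dataset(h5, "obs/n_umi/mask")
           rewrite_bool_dataset(h5, "obs/n_umi/mask", m[-1])
         }),
    list(rule = "sparse/indptr-monotone", path = "/obsp/knn",
         fn = function(h5) {
           ip <- as.integer(rhdf5::h5read(h5, "obsp/knn/indptr"))
           ip[2] <- ip[length(ip)] + 5L
           rewrite_int_dataset(h5, "obsp/knn/indptr", ip, "int64", enc = NULL)
         }),
    list(rule = "enc/bad-version", path = "/X",
         fn = function(h5) rewrite_attr(h5, "X", "encoding-version", "vX.Y"))
  )
  for (cs in cases) {
    bad <- copy_and_corrupt(f, cs$fn)
    rep <- validateH5AD(bad)
    expect_false(isConformant(rep), info = cs$rule)
    v <- violations(rep)
    hit <- v[v$rule == cs$rule, , drop = FALSE]
    expect_gt(nrow(hit), 0)
    expect_true(any(grepl(sub("^/", "", cs$path), hit$path)),
                info = paste(cs$rule, "->", paste(hit$path, collapse = ",")))
  }
})

test_that("an unreadable file raises an error, not a violation list", {
  expect_error(validateH5AD(tempfile()), "does not exist")
  txt <- tempfile()
  writeLines("plain text", txt)
  expect_error(validateH5AD(txt), "not an HDF5 file")
})

test_that("diff(f, f) is empty for every corpus file", {
  for (f in corpus_files()) {
    expect_true(isEqual(diffH5AD(f, f)), info = basename(f))
  }
})

test_that("single-element perturbations are localized to their exact path", {
  f <- base_file()
  perturbations <- list(
    list(path = "/obs/n_genes", kind = "value_mismatch",
         fn = function(h5) {
           x <- as.integer(rhdf5::h5read(h5, "obs/n_genes"))
           x[3] <- x[3] + 1L
           rewrite_int_dataset(h5, "obs/n_genes", x)
         }),
    list(path = "/obs/score", kind = "value_mismatch",
         fn = function(h5) {
           x <- as.numeric(rhdf5::h5read(h5, "obs/score"))
           x[1] <- x[1] + 0.5
           rhdf5::h5delete(h5, "obs/score")
           h5adkit:::.h5_write_dataset(h5, "obs/score", x, "double")
           h5adkit:::.write_encoding_attrs(h5, "obs/score", "array")
         }),
    list(path = "/X/data", kind = "value_mismatch", diff_path = "/X",
         fn = function(h5) {
           x <- as.numeric(rhdf5::h5read(h5, "X/data"))
           x[2] <- x[2] * 2 + 1
           rhdf5::h5delete(h5, "X/data")
           h5adkit:::.h5_write_dataset(h5, "X/data", x, "double")
         }),
    list(path = "/obs/celltype", kind = "value_mismatch",
         fn = function(h5) {
           cd <- as.integer(rhdf5::h5read(h5, "obs/celltype/codes"))
           cd[1] <- (cd[1] + 1L) %% 2L
           rewrite_int_dataset(h5, "obs/celltype/codes", cd)
         }),
    list(path = "/uns/params/alpha", kind = "value_mismatch",
         fn = function(h5) {
           rhdf5::h5delete(h5, "uns/params/alpha")
           h5adkit:::.h5_write_dataset(h5, "uns/params/alpha", 0.1, "double",
                                       scalar = TRUE)
           h5adkit:::.write_encoding_attrs(h5, "uns/params/alpha",
                                           "numeric-scalar")
         }),
    list(path = "/obsm/pca", kind = "value_mismatch",
         fn = function(h5) {
           x <- h5adkit:::.h5_read_dataset(h5, "obsm/pca")
           x[1, 1] <- x[1, 1] + 1
           rhdf5::h5delete(h5, "obsm/pca")
           h5adkit:::.h5_write_dataset(h5, "obsm/pca", x, "double")
           h5adkit:::.write_encoding_attrs(h5, "obsm/pca", "array")
         }),
    list(path = "/var/highly_variable", kind = "value_mismatch",
         fn = function(h5) {
           x <- h5adkit:::.h5_read_dataset(h5, "var/highly_variable")
           x[1] <- !x[1]
           rewrite_bool_dataset(h5, "var/highly_variable", x)
         }),
    list(path = "/uns/pipeline", kind = "value_mismatch",
         fn = function(h5) {
           rhdf5::h5delete(h5, "uns/pipeline")
           h5adkit:::.h5_write_dataset(h5, "uns/pipeline", "other", "string",
                                       scalar = TRUE)
           h5adkit:::.write_encoding_attrs(h5, "uns/pipeline", "string")
         }),
    list(path = "/uns/version", kind = "missing", remove = TRUE,
         fn = function(h5) rhdf5::h5delete(h5, "uns/version")),
    list(path = "/obs/celltype", kind = "attr_mismatch",
         fn = function(h5) {
           delete_attr(h5, "obs/celltype", "ordered")
           oid <- rhdf5::H5Oopen(h5, "obs/celltype")
           rhdf5::h5writeAttribute(1L, oid, "ordered")
           rhdf5::H5Oclose(oid)
         }),
    list(path = "/layers/logcounts", kind = "shape_mismatch",
         fn = function(h5) {
           x <- h5adkit:::.h5_read_dataset(h5, "layers/logcounts")
           rhdf5::h5delete(h5, "layers/logcounts")
           h5adkit:::.h5_write_dataset(h5, "layers/logcounts",
                                       x[-1, , drop = FALSE], "double")
           h5adkit:::.write_encoding_attrs(h5, "layers/logcounts", "array")
         })
  )
  for (p in perturbations) {
    pert <- copy_and_corrupt(f, p$fn)
    d <- diffH5AD(f, pert)
    entries <- diffEntries(d)
    expect_false(isEqual(d), info = p$path)
    target <- if (!is.null(p$diff_path)) p$diff_path else p$path
    expect_identical(nrow(entries), 1L,
                     info = paste(p$path, "->",
                                  paste(entries$path, collapse = ",")))
    expect_identical(entries$path, target)
    if (!isTRUE(p$remove)) {
      expect_identical(entries$kind, p$kind, info = p$path)
    } else {
      expect_true(entries$kind %in% c("missing_left", "missing_right"))
    }
  }
})

test_that("diff is symmetric up to mirrored missing kinds", {
  f <- base_file()
  pert <- copy_and_corrupt(f, function(h5) rhdf5::h5delete(h5, "uns/version"))
  d1 <- diffEntries(diffH5AD(f, pert))
  d2 <- diffEntries(diffH5AD(pert, f))
  expect_identical(d1$path, d2$path)
  mirror <- c(missing_left = "missing_right", missing_right = "missing_left")
  expect_identical(unname(mirror[d1$kind]), d2$kind)
})

test_that("numeric tolerance separates equal-within-tol from different", {
  f <- base_file()
  pert <- copy_and_corrupt(f, function(h5) {
    x <- as.numeric(rhdf5::h5read(h5, "obs/score"))
    x[1] <- x[1] + 1e-9
    rhdf5::h5delete(h5, "obs/score")
    h5adkit:::.h5_write_dataset(h5, "obs/score", x, "double")
    h5adkit:::.write_encoding_attrs(h5, "obs/score", "array")
  })
  expect_false(isEqual(diffH5AD(f, pert)))                 # default tol 0
  expect_true(isEqual(diffH5AD(f, pert, tol = 1e-6)))
})

test_that("dense vs sparse storage is equal unless strictEncoding", {
  ad <- corpus_container("csr_x")
  dense <- ad[seq_len(nObs(ad)), seq_len(nVar(ad))]   # independent copy
  adX(dense) <- as.matrix(adX(ad))
  f1 <- tempfile(fileext = ".h5ad")
  f2 <- tempfile(fileext = ".h5ad")
  writeH5AD(ad, f1)
  writeH5AD(dense, f2)
  expect_true(isEqual(diffH5AD(f1, f2)))
  strict <- diffH5AD(f1, f2, strictEncoding = TRUE)
  expect_false(isEqual(strict))
  e <- diffEntries(strict)
  expect_identical(e$path, "/X")
  expect_identical(e$kind, "type_mismatch")
})
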