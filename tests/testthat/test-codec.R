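# Element codec: encode/decode round-trips per encoding, detection and
# legacy handling, structured errors.

codec_file <- function() {
  f <- tempfile(fileext = ".h5")
  rhdf5::h5createFile(f)
  f
}

roundtrip <- function(x, scalarOK = FALSE) {
  f <- codec_file()
  writeElement(x, f, "el", scalarOK = scalarOK)
  readElement(f, "el")
}

test_that("atomic vectors and arrays round-trip bit-exactly", {
  cases <- list(
    double = c(1.5, -2.25, 0, 1e-300, 1e300),
    double_special = c(1.5, NA_real_, NaN, Inf, -Inf),
    integer = c(-5L, 0L, 7L, .Machine$integer.max),
    logical = c(TRUE, FALSE, TRUE),
    character = c("a", "", "multi word", "tab\there"),
    unicode = c("αβγ", "日本語", "café"),
    empty_double = numeric(0),
    int_matrix = matrix(1:12, 3, 4),
    dbl_matrix = matrix(c(0.5, -1, 2, NA), 2, 2),
    lgl_matrix = matrix(c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE), 2, 3),
    array_3d = array(seq_len(24) + 0.5, dim = c(2, 3, 4))
  )
  for (nm in names(cases)) {
    got <- roundtrip(cases[[nm]])
    expect_identical(got, cases[[nm]], info = nm)
  }
})

test_that("NA_real_ survives a round-trip distinct from NaN", {
  got <- roundtrip(c(1, NA_real_, NaN))
  expect_true(is.na(got[2]) && !is.nan(got[2]))
  expect_true(is.nan(got[3]))
})

test_that("categoricals preserve codes, category order and ordered flag", {
  f1 <- factor(c("b", "a", "b", "a"), levels = c("b", "a"))
  expect_identical(roundtrip(f1), f1)
  f2 <- factor(c("low", NA, "high"), levels = c("low", "mid", "high"),
               ordered = TRUE)
  expect_identical(roundtrip(f2), f2)
  f3 <- factor(character(0), levels = c("x", "y"))
  expect_identical(roundtrip(f3), f3)
})

test_that("nullable integer and boolean vectors decode masked entries as NA", {
  expect_identical(roundtrip(c(1L, NA, 3L)), c(1L, NA, 3L))
  expect_identical(roundtrip(c(TRUE, NA, FALSE, NA)), c(TRUE, NA, FALSE, NA))
  expect_identical(roundtrip(rep(NA, 4)), rep(NA, 4))          # all masked
  expect_identical(roundtrip(c(NA_integer_, NA_integer_)),
                   c(NA_integer_, NA_integer_))
})

test_that("nullable encodings store paired values/mask datasets on disk", {
  f <- codec_file()
  writeElement(c(1L, NA, 3L), f, "n")
  expect_identical(detectEncoding(f, "n")$type, "nullable-integer")
  expect_identical(as.integer(h5adkit:::.h5_read_dataset(
    rhdf5::H5Fopen(f, flags = "H5F_ACC_RDONLY") -> h5, "n/values")),
    c(1L, 0L, 3L))
  expect_identical(h5adkit:::.h5_read_dataset(h5, "n/mask"),
                   c(FALSE, TRUE, FALSE))
  rhdf5::H5Fclose(h5)
})

test_that("sparse matrices round-trip in both orientations", {
  set.seed(7)
  m <- Matrix::rsparsematrix(6, 9, 0.3)
  csc <- as(as(m, "generalMatrix"), "CsparseMatrix")
  csr <- as(as(m, "generalMatrix"), "RsparseMatrix")
  expect_identical(roundtrip(csc), csc)
  expect_identical(roundtrip(csr), csr)
})

test_that("known CSR triple expands to the expected dense matrix", {
  # [[1,0,2],[0,3,0]] CSR: data=[1,2,3], indices=[0,2,1], indptr=[0,2,3]
  f <- codec_file()
  h5 <- rhdf5::H5Fopen(f)
  m <- matrix(c(1, 0, 2, 0, 3, 0), nrow = 2, byrow = TRUE)
  h5adkit:::.write_sparse(m, h5, "sp", "CSR")
  expect_identical(as.double(h5adkit:::.h5_read_dataset(h5, "sp/data")),
                   c(1, 2, 3))
  expect_identical(as.integer(h5adkit:::.h5_read_dataset(h5, "sp/indices")),
                   c(0L, 2L, 1L))
  expect_identical(as.integer(h5adkit:::.h5_read_dataset(h5, "sp/indptr")),
                   c(0L, 2L, 3L))
  rhdf5::H5Fclose(h5)
  back <- readElement(f, "sp")
  expect_s4_class(back, "dgRMatrix")
  expect_identical(unname(as.matrix(back)), m)
})

test_that("all-zero sparse matrices produce empty data and flat indptr", {
  f <- codec_file()
  h5 <- rhdf5::H5Fopen(f)
  h5adkit:::.write_sparse(matrix(0, 2, 3), h5, "z", "CSR")
  expect_identical(as.integer(h5adkit:::.h5_read_dataset(h5, "z/indptr")),
                   c(0L, 0L, 0L))
  expect_identical(length(h5adkit:::.h5_read_dataset(h5, "z/data")), 0L)
  rhdf5::H5Fclose(h5)
  expect_identical(unname(as.matrix(readElement(f, "z"))), matrix(0, 2, 3))
})

test_that("corrupt sparse triples yield path-addressed validation errors", {
  f <- codec_file()
  h5 <- rhdf5::H5Fopen(f)
  h5adkit:::.write_sparse(Matrix::rsparsematrix(4, 5, 0.5), h5, "sp", "CSR")
  rhdf5::H5Fclose(h5)
  # truncate indptr
  bad1 <- copy_and_corrupt(f, function(h5) {
    ip <- as.integer(rhdf5::h5read(h5, "sp/indptr"))
    rewrite_int_dataset(h5, "sp/indptr", ip[-length(ip)], "int64", enc = NULL)
  })
  expect_error(readElement(bad1, "sp"), "indptr",
               class = "h5adkit_validation_error")
  # index out of range
  bad2 <- copy_and_corrupt(f, function(h5) {
    ix <- as.integer(rhdf5::h5read(h5, "sp/indices"))
    ix[1] <- 99L
    rewrite_int_dataset(h5, "sp/indices", ix, "int64", enc = NULL)
  })
  expect_error(readElement(bad2, "sp"), "out of range",
               class = "h5adkit_validation_error")
})

test_that("dataframes preserve column order, types and index", {
  df <- data.frame(
    b_second = c(0.5, 1.5, 2.5),
    a_first = c(10L, 20L, 30L),
    cat = factor(c("x", "y", "x")),
    flag = c(TRUE, NA, FALSE),
    check.names = FALSE)
  f <- codec_file()
  h5 <- rhdf5::H5Fopen(f)
  h5adkit:::.write_dataframe(df, h5, "df", index = c("r1", "r2", "r3"))
  rhdf5::H5Fclose(h5)
  back <- readElement(f, "df")
  expect_identical(names(back), names(df))   # order kept, not alphabetized
  expect_identical(attr(back, "h5ad_index"), c("r1", "r2", "r3"))
  for (cn in names(df)) expect_identical(back[[cn]], df[[cn]], info = cn)
})

test_that("a zero-column dataframe keeps its index", {
  f <- codec_file()
  h5 <- rhdf5::H5Fopen(f)
  h5adkit:::.write_dataframe(as.data.frame(matrix(nrow = 2, ncol = 0)),
                             h5, "df", index = c("c1", "c2"))
  rhdf5::H5Fclose(h5)
  back <- readElement(f, "df")
  expect_identical(ncol(back), 0L)
  expect_identical(attr(back, "h5ad_index"), c("c1", "c2"))
})

test_that("duplicate dataframe column names are rejected", {
  df <- data.frame(a = 1:2, b = 3:4)
  names(df) <- c("a", "a")
  f <- codec_file()
  expect_error(writeElement(df, f, "df"), "duplicate column names")
})

test_that("mappings round-trip recursively, to depth 6 and when empty", {
  deep <- list(a = list(b = list(c = list(d = list(e = list(f = "leaf"))))))
  expect_identical(roundtrip(deep, scalarOK = TRUE), deep)
  expect_identical(roundtrip(list(), scalarOK = TRUE), list())
  mix <- list(colors = c("#aaa", "#bbb"),
              params = list(flag = TRUE, k = 15L, method = "umap"))
  expect_identical(roundtrip(mix, scalarOK = TRUE), mix)
})

test_that("length-1 values in mappings are written as true scalars", {
  f <- codec_file()
  writeElement(list(k = 15L, name = "x", pi = 3.14, yes = TRUE), f, "u",
               scalarOK = TRUE)
  h5 <- rhdf5::H5Fopen(f, flags = "H5F_ACC_RDONLY")
  for (p in c("u/k", "u/name", "u/pi", "u/yes")) {
    expect_identical(length(h5adkit:::.h5_dims(h5, p)), 0L, info = p)
  }
  rhdf5::H5Fclose(h5)
  expect_identical(detectEncoding(f, "u/name")$type, "string")
  expect_identical(detectEncoding(f, "u/k")$type, "numeric-scalar")
})

test_that("unnamed mapping entries are rejected", {
  f <- codec_file()
  expect_error(writeElement(list(1, 2), f, "u"), "names")
})

test_that("detectEncoding reads the declared type and version", {
  f <- codec_file()
  writeElement(Matrix::rsparsematrix(3, 3, 0.5), f, "sp")
  d <- detectEncoding(f, "sp")
  expect_identical(d$type, "csc_matrix")
  expect_identical(d$version, "0.1.0")
  writeElement(c(1, 2), f, "arr")
  expect_identical(detectEncoding(f, "arr")$type, "array")
})

test_that("unknown encoding types are rejected with the path in the error", {
  f <- codec_file()
  writeElement(c(1, 2), f, "arr")
  bad <- copy_and_corrupt(f, function(h5) {
    rewrite_attr(h5, "arr", "encoding-type", "bogus")
  })
  err <- tryCatch(readElement(bad, "arr"), error = identity)
  expect_s3_class(err, "h5adkit_unknown_encoding")
  expect_match(conditionMessage(err), "arr")
  expect_match(conditionMessage(err), "bogus")
})

test_that("legacy elements without attributes follow the declared policy", {
  f <- codec_file()
  h5 <- rhdf5::H5Fopen(f)
  # raw datasets/groups without any encoding attributes
  h5adkit:::.h5_write_dataset(h5, "plain", c(1.5, 2.5), "double")
  h5adkit:::.h5_create_group(h5, "grp")
  h5adkit:::.h5_write_dataset(h5, "grp/data", c(1, 2), "double")
  h5adkit:::.h5_write_dataset(h5, "grp/indices", c(0L, 1L), "int64")
  h5adkit:::.h5_write_dataset(h5, "grp/indptr", c(0L, 1L, 2L), "int64")
  h5adkit:::.h5_write_attr(h5, "grp", "shape", c(2L, 2L), scalar = FALSE)
  rhdf5::H5Fclose(h5)
  expect_warning(d <- detectEncoding(f, "plain", legacy = "infer"),
                 "inferred")
  expect_identical(d$type, "array")
  expect_warning(ds <- detectEncoding(f, "grp", legacy = "infer"), "inferred")
  expect_identical(ds$type, "csr_matrix")
  err <- tryCatch(detectEncoding(f, "plain", legacy = "error"),
                  error = identity)
  expect_s3_class(err, "h5adkit_legacy_error")
  expect_match(conditionMessage(err), "plain")
})
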