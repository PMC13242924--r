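# Deterministic synthetic fixtures.
#
# The generator exists so that every test suite (codec round-trips, sparse
# oracle, converters, validator/diff, backed mode) runs without downloading
# anything. Values are drawn from simple distributions -- Poisson-like
# integers for counts, standard normals for embeddings -- because the
# format tests only care about types, shapes and encodings, not biology.
# Determinism (same spec + seed -> deep-equal container) is the contract.

.FIXTURE_FEATURES <- c(
  "dense_X", "sparse_csr_X", "sparse_csc_X", "layers", "raw",
  "categoricals", "nullable_cols", "nested_uns", "obsm_varm_pair",
  "obsp", "varp", "empty_slots", "unicode_strings", "missing_values",
  "duplicate_names"
)

#' Describe a synthetic fixture
#'
#' @param nObs,nVar Container dimensions.
#' @param seed RNG seed; the same spec always generates a deep-equal
#'   container.
#' @param features Character vector of feature toggles; see
#'   `h5adkit:::.FIXTURE_FEATURES`. At most one `*_X` toggle may be given
#'   (none means the container has no `X`).
#' @return A `fixture_spec` list.
#' @seealso [generateFixture()], [fixtureCorpus()]
#' @export
fixtureSpec <- function(nObs = 50L, nVar = 20L, seed = 1L,
                        features = character(0)) {
  bad <- setdiff(features, .FIXTURE_FEATURES)
  if (length(bad) > 0L) {
    stop("unknown feature toggle(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  x_toggles <- intersect(features, c("dense_X", "sparse_csr_X",
                                     "sparse_csc_X"))
  if (length(x_toggles) > 1L) {
    stop("contradictory toggles: at most one of dense_X/sparse_csr_X/",
         "sparse_csc_X", call. = FALSE)
  }
  structure(list(nObs = as.integer(nObs), nVar = as.integer(nVar),
                 seed = as.integer(seed), features = features),
            class = "fixture_spec")
}

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.rand_counts <- function(n, v) {
  m <- matrix(stats::rpois(n * v, lambda = 2) *
                stats::rbinom(n * v, 1, 0.5), nrow = n, ncol = v)
  storage.mode(m) <- "integer"
  m
}

# HDF5 groups iterate in byte-wise name order; emitting mapping keys in
# that order makes generate -> write -> read an exact identity
.sort_keys <- function(x) {
  if (length(x) > 1L) x[order(names(x), method = "radix")] else x
}

#' Generate a synthetic AnnData container
#'
#' Deterministically builds a container exhibiting exactly the features
#' toggled in the spec; the output always passes [validateAnnData()].
#'
#' @param spec A [fixtureSpec()].
#' @return An [AnnData()] container.
#' @export
#' @examples
#' ad <- generateFixture(fixtureSpec(10, 6, seed = 7,
#'                                   features = c("dense_X", "layers")))
#' dim(ad)
generateFixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  .with_seed(spec$seed, {
    n <- spec$nObs
    v <- spec$nVar
    has <- function(f) f %in% spec$features

    obs_names <- sprintf("cell%d", seq_len(n))
    if (has("duplicate_names") && n >= 2L) obs_names[2] <- obs_names[1]
    var_names <- sprintf("gene%d", seq_len(v))

    X <- NULL
    if (has("dense_X")) {
      X <- .rand_counts(n, v)
    } else if (has("sparse_csr_X")) {
      X <- as(as(Matrix::Matrix(.rand_counts(n, v), sparse = TRUE),
                 "generalMatrix"), "RsparseMatrix")
    } else if (has("sparse_csc_X")) {
      X <- as(as(Matrix::Matrix(.rand_counts(n, v), sparse = TRUE),
                 "generalMatrix"), "CsparseMatrix")
    }

    layers <- list()
    if (has("layers")) {
      layers$logcounts <- matrix(log1p(stats::rpois(n * v, 3)), nrow = n)
      layers$scaled <- as(as(Matrix::Matrix(
        matrix(stats::rnorm(n * v), nrow = n) *
          stats::rbinom(n * v, 1, 0.3), sparse = TRUE),
        "generalMatrix"), "CsparseMatrix")
    }

    obs <- data.frame(n_genes = as.integer(stats::rpois(n, 60)),
                      score = stats::runif(n))
    lab <- sample(c("alpha", "beta", "gamma"), n, replace = TRUE)
    if (has("unicode_strings")) {
      lab <- sample(c("ɑ-细胞", "β-cellule", "γ🧬"), n, replace = TRUE)
    }
    obs$label <- lab
    obs$pass_qc <- stats::runif(n) > 0.2
    if (has("categoricals")) {
      obs$celltype <- factor(sample(c("B", "T", "NK"), n, replace = TRUE))
      obs$grade <- factor(sample(c("low", "mid", "high"), n, replace = TRUE),
                          levels = c("low", "mid", "high"), ordered = TRUE)
    }
    if (has("nullable_cols")) {
      ni <- as.integer(stats::rpois(n, 100))
      ni[sample(n, max(1, n %/% 5))] <- NA_integer_
      obs$n_umi <- ni
      nb <- stats::runif(n) > 0.5
      nb[sample(n, max(1, n %/% 4))] <- NA
      obs$outlier <- nb
    }
    if (has("missing_values")) {
      sc <- stats::rnorm(n)
      sc[sample(n, max(1, n %/% 5))] <- NA_real_
      if (n >= 2) sc[2] <- NaN
      obs$dropout <- sc
      f <- factor(sample(c("x", "y"), n, replace = TRUE))
      f[sample(n, max(1, n %/% 4))] <- NA
      obs$batch <- f
    }
    if (n == 0L) obs <- obs[0, , drop = FALSE]

    var <- data.frame(highly_variable = stats::runif(v) > 0.5,
                      mean_expr = stats::rnorm(v, 2))
    if (v == 0L) var <- var[0, , drop = FALSE]

    obsm <- list()
    varm <- list()
    if (has("obsm_varm_pair")) {
      obsm$pca <- matrix(stats::rnorm(n * 5L), nrow = n)
      varm$pca <- matrix(stats::rnorm(v * 5L), nrow = v)
      obsm$X_umap <- matrix(stats::rnorm(n * 2L), nrow = n)
      varm$dispersions <- matrix(stats::rnorm(v * 3L), nrow = v)
    }
    if (has("empty_slots")) {
      obsm$empty <- matrix(numeric(0), nrow = n, ncol = 0)
    }

    obsp <- list()
    if (has("obsp")) {
      obsp$knn <- as(as(Matrix::rsparsematrix(n, n, 0.2), "generalMatrix"),
                     "CsparseMatrix")
      obsp$distances <- as(as(Matrix::rsparsematrix(n, n, 0.2),
                              "generalMatrix"), "RsparseMatrix")
    }
    varp <- list()
    if (has("varp")) {
      varp$gene_cor <- matrix(stats::rnorm(v * v), nrow = v)
      varp$coexpr <- as(as(Matrix::rsparsematrix(v, v, 0.2),
                           "generalMatrix"), "CsparseMatrix")
    }

    uns <- list(
      pipeline = "h5adkit-fixture",
      params = list(alpha = 0.05, iterations = 25L, normalized = TRUE),
      thresholds = c(0.1, 0.5, 0.9),
      version = 1L
    )
    if (has("nested_uns")) {
      uns$nested <- list(l1 = list(l2 = list(l3 = list(l4 = list(
        l5 = list(l6 = "bottom", marker = 6L))))))
    }
    if (has("unicode_strings")) {
      uns$notes <- c("细胞注释", "ünïcode ✓")
    }
    if (has("empty_slots")) {
      uns$empty <- list()
    }
    uns <- .sort_keys(uns)

    raw <- NULL
    if (has("raw")) {
      vr <- v + 5L
      raw <- list(
        X = as(as(Matrix::Matrix(.rand_counts(n, vr), sparse = TRUE),
                  "generalMatrix"), "RsparseMatrix"),
        var = data.frame(retained = c(stats::runif(v) > 0.1,
                                      rep(FALSE, 5L))),
        varNames = sprintf("gene%d", seq_len(vr)),
        varm = list(weights = matrix(stats::rnorm(vr * 2L), nrow = vr))
      )
    }

    AnnData(X = X, layers = .sort_keys(layers), obs = obs, var = var,
            obsNames = obs_names, varNames = var_names,
            obsm = .sort_keys(obsm), varm = .sort_keys(varm),
            obsp = .sort_keys(obsp), varp = .sort_keys(varp),
            uns = uns, raw = raw)
  })
}

#' The named fixture corpus
#'
#' A fixed set of fixture specs jointly covering every supported element
#' encoding, every container slot, and the enumerated edge cases (0 obs,
#' 0 var, no X, unicode, missing values, duplicate names). The corpus is
#' stable across runs and releases of the test data.
#'
#' @param nObs,nVar Base dimensions used by most fixtures.
#' @return Named list of [fixtureSpec()] objects.
#' @export
fixtureCorpus <- function(nObs = 25L, nVar = 12L) {
  sp <- function(features, seed, n = nObs, v = nVar) {
    fixtureSpec(n, v, seed = seed, features = features)
  }
  list(
    minimal        = sp(character(0), 101L),
    dense_x        = sp("dense_X", 102L),
    csr_x          = sp("sparse_csr_X", 103L),
    csc_x          = sp("sparse_csc_X", 104L),
    layers         = sp(c("dense_X", "layers"), 105L),
    categoricals   = sp(c("dense_X", "categoricals"), 106L),
    nullable       = sp(c("dense_X", "nullable_cols"), 107L),
    nested_uns     = sp(c("dense_X", "nested_uns"), 108L),
    obsm_varm      = sp(c("dense_X", "obsm_varm_pair"), 109L),
    pairwise       = sp(c("sparse_csr_X", "obsp", "varp"), 110L),
    raw            = sp(c("sparse_csr_X", "raw"), 111L),
    empty_slots    = sp(c("dense_X", "empty_slots"), 112L),
    unicode        = sp(c("dense_X", "unicode_strings"), 113L),
    missing_values = sp(c("dense_X", "categoricals", "nullable_cols",
                          "missing_values"), 114L),
    duplicate_names = sp(c("dense_X", "duplicate_names"), 115L),
    zero_obs       = sp("dense_X", 116L, n = 0L),
    zero_var       = sp("dense_X", 117L, v = 0L),
    zero_by_zero   = sp(character(0), 118L, n = 0L, v = 0L),
    everything     = sp(c("sparse_csr_X", "layers", "raw", "categoricals",
                          "nullable_cols", "nested_uns", "obsm_varm_pair",
                          "obsp", "varp", "empty_slots", "unicode_strings",
                          "missing_values"), 119L)
  )
}

#' Write the fixture corpus as H5AD files
#'
#' @param dir Output directory (created if needed).
#' @param corpus A corpus as returned by [fixtureCorpus()].
#' @return Named character vector of file paths.
#' @export
writeFixtureCorpus <- function(dir, corpus = fixtureCorpus()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(corpus), function(nm) {
    p <- file.path(dir, paste0(nm, ".h5ad"))
    writeH5AD(generateFixture(corpus[[nm]]), p, overwrite = TRUE)
    p
  }, character(1))
  paths
}
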