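# h5adkit

Native H5AD (AnnData) input/output, containers and converters for
single-cell data in R.

Single-cell transcriptomics datasets are widely stored as H5AD files —
the HDF5 serialization of the Python scverse AnnData container: a central
observations × variables matrix `X` plus aligned metadata slots (`obs`,
`var`, `layers`, `obsm`/`varm`, `obsp`/`varp`, `uns`, `raw`). Using those
files from R usually means driving a Python process through a
foreign-function interface. h5adkit removes that dependency: it reads and
writes H5AD directly through `rhdf5`, following the AnnData on-disk
specification's per-element `encoding-type`/`encoding-version` scheme, so
files interoperate with the reference implementation in both directions.

For whom: R users analysing scverse-produced data with Bioconductor or
Seurat tooling, and pipeline authors who need a dependable, auditable
bridge between the three ecosystems.

What's in the box:

* **Codec** — every element encoding of the on-disk format (dense and
  CSR/CSC sparse matrices, dataframes with preserved column order,
  categoricals, nullable integer/boolean vectors, UTF-8 strings, scalars,
  nested mappings), with a legacy-inference policy for files predating
  the encoding attributes.
* **`AnnData` container** — S4 with reference semantics, full shape
  validation (`n_obs × n_var` everywhere it must hold), subsetting that
  slices every slot consistently, and a file-backed variant that decodes
  metadata eagerly and leaves matrices on disk until materialized
  (`toMemory()`).
* **Converters** — `toSCE()`/`fromSCE()` and `toSeurat()`/`fromSeurat()`
  with the standard slot correspondence (matrices transposed to
  features × cells), per-slot map overrides (`defaultMap()`), and a
  `LossReport` recording everything dropped, stashed or renamed — e.g.
  `varp`, which has no Seurat slot, is stashed under a reserved `misc`
  key and recovered on the way back.
* **Validator and semantic diff** — `validateH5AD()` checks every
  structural invariant of the format with path-addressed rule ids;
  `diffH5AD()` compares *decoded* content (never bytes) and localizes
  each difference to its exact element path.
* **Fixture generator** — deterministic synthetic containers covering
  every encoding and edge case, so all tests run with no downloads.
* **CLI** — `inst/cli/h5adtool` with `validate`, `diff`, `info` and
  `convert` subcommands and strict exit-code contracts.

## Worked example

```r
library(h5adkit)

ad <- generateFixture(fixtureSpec(nObs = 100, nVar = 50, seed = 1,
  features = c("sparse_csr_X", "layers", "categoricals",
               "obsm_varm_pair", "obsp")))
ad
#> AnnData object with n_obs x n_var = 100 x 50
#>     X: dgRMatrix
#>     layers: logcounts, scaled
#>     obsm: X_umap, pca
#>     varm: dispersions, pca
#>     obsp: distances, knn
#>     obs: n_genes, score, label, pass_qc, celltype, grade
#>     var: highly_variable, mean_expr
#>     uns: params, pipeline, thresholds, version

f <- file.path(tempdir(), "example.h5ad")
writeH5AD(ad, f)
validateH5AD(f)
#> ValidationReport: conformant < /tmp/.../example.h5ad >

sce <- toSCE(ad)
#> Warning: varm:dispersions has no first-class destination;
#>          stashed under metadata$.unmapped$varm
sce
#> class: SingleCellExperiment
#> dim: 50 100
#> assays(3): X logcounts scaled
#> reducedDimNames(2): X_umap pca
#> ...
```

The SCE is 50 × 100 — the transpose of the 100 × 50 container, because
Bioconductor puts features in rows. The warning is mirrored in the
attached report: the `varm` entry `dispersions` matches no `obsm` key, so
it cannot ride a reduced dimension and is stashed (not lost):

```r
lossReport(sce)
#> LossReport: 0 dropped, 1 stashed, 0 renamed
#>   stashed varm:dispersions -> metadata$.unmapped$varm

so <- toSeurat(ad)
lossReport(so)
#> LossReport: 0 dropped, 1 stashed, 1 renamed
#>   stashed varm:dispersions -> misc$.unmapped$varm
#>   renamed obsm:X_umap -> umap

back <- fromSeurat(so)
all.equal(as.matrix(adX(back)), as.matrix(adX(ad)))
#> [1] TRUE

head(h5adInfo(f), 4)
#>                path   encoding        shape
#> 1                /X csr_matrix     100 x 50
#> 2           /layers       dict 2 element(s)
#> 3 /layers/logcounts      array     100 x 50
#> 4    /layers/scaled csc_matrix     100 x 50
```

The `renamed` entry records that the conventional `X_umap` key became the
Seurat reduction `umap`; `fromSeurat()` restores the original key, and
the round-trip is an identity on every mapped slot.

From a shell, the same tooling:

```sh
Rscript inst/cli/h5adtool validate example.h5ad     # exit 0 if conformant
Rscript inst/cli/h5adtool diff a.h5ad b.h5ad        # exit 1 on differences
Rscript inst/cli/h5adtool convert in.h5ad out.rds --to sce
```

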