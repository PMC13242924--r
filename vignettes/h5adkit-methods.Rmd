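---
title: "h5adkit: design and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{h5adkit: design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

Single-cell transcriptomics splits across three ecosystems with
incompatible in-memory containers: AnnData (Python/scverse), the
SingleCellExperiment (Bioconductor) and the Seurat object. The H5AD file
format -- the HDF5 serialization of AnnData -- has become the de facto
exchange format, but most R routes to it go through a Python process via a
foreign-function interface, which means maintaining a second language
runtime and duplicating data in memory. h5adkit reads and writes H5AD
natively in R through rhdf5, provides an R-side AnnData container, and
converts to and from the two R ecosystems with explicit, auditable slot
maps.

# The on-disk codec

Every element in an H5AD file is tagged with `encoding-type` and
`encoding-version` attributes. The codec implements the encodings at the
versions currently emitted by the reference implementation
(`encodingRegistry()`): `array` and `string-array` (0.2.0), `string` and
`numeric-scalar` (0.2.0), `csr_matrix`/`csc_matrix` (0.1.0), `dataframe`
(0.2.0), `categorical` (0.2.0), `nullable-integer`/`nullable-boolean`
(0.1.0), `dict` (0.1.0) and the `raw` group (0.1.0). The registry is a
single constant so that new versions can be added in one place.

Decoded R representations:

| encoding            | R value                                          |
|---------------------|--------------------------------------------------|
| array               | numeric/integer/logical vector, matrix or array  |
| string-array        | character vector (variable-length UTF-8)         |
| string / numeric-scalar | length-1 vector                              |
| csr_matrix / csc_matrix | `Matrix::dgRMatrix` / `Matrix::dgCMatrix`    |
| categorical         | factor (ordered when flagged)                    |
| nullable-integer/-boolean | integer / logical vector with `NA`         |
| dataframe           | data.frame, column order preserved               |
| dict                | named list, arbitrary nesting                    |

## Orientation

HDF5 stores arrays row-major and R column-major. All reads and writes go
through a single utility layer that transposes (`aperm`) so that the
*logical* element `[i, j]` -- the element the reference implementation
reports at `[i, j]` -- is identical regardless of which writer produced
the file. This is asserted directly against files written by the Python
implementation in the interoperability test.

## Missing values

* categorical code `-1` decodes to a factor `NA` and vice versa;
* a nullable mask position decodes to `NA`; on write, `NA` in an integer
  or logical vector selects the nullable encoding automatically;
* floating-point `NaN` and R's `NA_real_` are written bit-for-bit (no
  arithmetic is performed), so a float round-trip is lossless. `NA_real_`
  is itself a NaN with a distinguished payload and survives unchanged
  through R; other readers see an ordinary NaN. Floating NaN is *not*
  converted to a nullable mask -- a lossless float round-trip wins.

## Scalars

Zero-dimensional datasets decode to plain length-1 vectors. On write the
rule is contextual: inside mappings (`uns` and nested dicts) a length-1
atomic vector without a `dim` attribute is written as a true scalar
(`string`/`numeric-scalar` encoding); dataframe columns and matrix slots
are always written as arrays, so a one-row table never degenerates. The
rule makes `decode(encode(x))` an identity at the R level; a length-1
on-disk *array* re-encodes as a scalar, which every reader treats
identically.

## Key order

HDF5 iterates group members in name order unless a link-creation-order
property was set at creation; neither the available rhdf5 API nor the
reference writer records creation order, so mapping (`dict`/`uns`) key
order is treated as non-semantic: keys come back in byte-wise name order.
Dataframe column order *is* semantic and is preserved exactly through the
`column-order` attribute. The fixture generator emits mapping keys already
in byte-wise order so that generate-write-read is a strict identity.

## Known benign byte-level deviations

Interoperability is defined at the decoded level; three dtype-level
differences from the reference writer exist and are harmless by
construction (both readers decode them identically, verified in tests):

* integer datasets are written as 32-bit (sparse `indices`/`indptr` as
  64-bit, per the format's large-matrix allowance) while the reference
  may choose 8- or 64-bit; values outside R's integer range are read back
  as doubles with a warning;
* boolean *datasets* are written as the same FALSE/TRUE enum h5py uses,
  but boolean *attributes* (the categorical `ordered` flag) are written
  as int 0/1 because the HDF5 binding cannot create enum attributes; the
  reference reader coerces the attribute with `bool()` either way;
* datasets are gzip-compressed at level 4 by default (a writer option
  disables it); chunking layout is not byte-compatible with h5py's
  heuristics.

# The container

`AnnData()` is an S4 class wrapping an environment, which gives it
reference semantics: every handle to the same container observes
mutations made through any other handle, matching the Python interface's
behaviour (the same contract the reference R implementation obtains from
R6). Subsetting with `[` creates an independent container.

All shape invariants -- `X` and layers `n_obs x n_var`, `obsm`/`varm`
first dimensions, square `obsp`/`varp`, table row counts, axis-name
lengths, `raw` sharing `n_obs` while differing in variables -- are
enforced at construction and on every slot replacement; a failed
replacement rolls back, so a container can never be observed invalid.

Duplicate axis names are allowed (the format allows them). Because R
data.frames forbid duplicate rownames, axis names are stored alongside
the table rather than as rownames; the accessors present them as rownames
whenever they are unique. The on-disk index column name (usually
`_index`) travels with the container and is restored on write.

Backed mode (`readH5AD(..., mode = "backed")`) decodes `obs`, `var`,
`uns`, the axis names and a slot inventory eagerly; matrix-bearing slots
stay on disk until an accessor or `toMemory()` touches them, and are then
cached on the handle. Backed handles are read-only -- saving goes through
`toMemory()` and `writeH5AD()` to a new file, which matches the
read-analyze-save-new-file workflow the format encourages. The package
keeps an instrumentation log of dataset reads (`datasetReadLog()`) purely
so the laziness contract is testable.

`writeH5AD()` validates before writing a byte, assembles the file at a
temporary path and renames it into place, so a failed write never leaves
a partial file. Absent optional slots are omitted from the file rather
than written empty; sparse matrices keep their orientation and dense
stays dense -- there is no silent densification.

# Converters

Both directions of both conversions follow a single default map
(`defaultMap()`), the standard correspondence between the three layouts:

| AnnData | SingleCellExperiment | Seurat v5 |
|---------|----------------------|-----------|
| X, layers | assays (transposed) | assay layers (transposed) |
| obs / var | colData / rowData | cell-level / assay-level metadata |
| obsm / varm | reducedDims (+ loadings) | reductions (+ loadings) |
| obsp | colPairs | graphs |
| varp | rowPairs | *(stashed -- no Seurat slot)* |
| uns | metadata | misc |
| raw | altExp "raw" | *(stashed)* |

Matrix slots are transposed exactly (cells as columns in the R
ecosystems); the transposition invariant is asserted element-for-element
in the tests. Everything a conversion cannot place first-class is either
*stashed* under a reserved key (`metadata[[".unmapped"]]` /
`Misc(x)[[".unmapped"]]`) or *dropped*, and each such event is recorded
in a `LossReport` attached to the result (`lossReport()`), together with
every rename. The accounting is conservative: placed + dropped + stashed
always equals the number of populated source entries.

Design choices where the layouts underdetermine the mapping:

* **Seurat X layer name**: `"counts"` when `X` is integer-valued
  (every entry equals its rounding), else `"data"`; overridable.
* **Loadings pairing**: a `varm` key attaches as the loadings of a
  reduced dimension when it matches the `obsm` key exactly (SCE, via
  `LinearEmbeddingMatrix`) or after normalization (Seurat, where the
  conventional `X_` prefix is stripped from reduction names); unmatched
  `varm` entries are stashed. The pairing rule is the package's own --
  the layouts record no linkage.
* **Seurat `raw`**: the Seurat layer system can technically hold a
  ragged unfiltered matrix, but attaching an arbitrary feature set to an
  existing assay is fragile; `raw` is stashed instead and recovered by
  the inverse conversion.
* **Name legality**: Seurat requires unique, underscore-free cell and
  feature names; repairs are applied only for Seurat targets and every
  repair is recorded. SCE imposes no such rule and no repair is made.
* **Dataframe-valued `obsm`**: numeric-only columns are coerced to a
  matrix with a warning; mixed-type entries are stashed.
* **Round-trip markers**: the stash also carries small markers (which
  layer held `X`, the original sparse orientation or density of
  matrices that the target coerces to column-sparse, original
  reduction keys) so that the inverse conversion is an exact identity,
  not merely value-equal. Seurat's automatic `orig.ident`/`nCount_*`/
  `nFeature_*` metadata columns are removed by the inverse conversion
  unless requested.
* **Ambiguous altExps**: only the alternative experiment named `"raw"`
  reverse-maps to `raw`; any other altExp may be a paired measurement
  (CITE-seq, spike-ins) and is surfaced with a warning and a report
  entry instead of being guessed at.

# Validator and diff

`validateH5AD()` walks a file and checks the root layout plus every
structural invariant of the encodings (sparse `indptr` length,
monotonicity and endpoints, index ranges, categorical code ranges and
category uniqueness, dataframe column lengths and `column-order`
consistency, nullable value/mask pairing, scalar ranks, version syntax).
Violations carry the element path and a stable rule id; an unreadable
file is an error, not a violation list.

`diffH5AD()` compares *decoded* elements, never bytes, so the
binding-level differences listed above do not register. Dataframes are
compared per column and mappings per key, which localizes any discrepancy
to its exact slash path. Numeric comparison uses an absolute tolerance
(default 0); `strictEncoding = TRUE` additionally requires the declared
encodings to match, turning a dense-vs-sparse storage difference into a
reported `type_mismatch`. The diff is symmetric up to mirrored
`missing_left`/`missing_right` kinds.

# The fixture generator

`generateFixture()`/`fixtureCorpus()` produce synthetic containers
covering every encoding and the edge cases (0 observations, 0 variables,
no `X`, unicode strings, all-missing columns, duplicate names). Counts
are Poisson-like integers, embeddings standard normals, graphs sparse
random matrices -- the exact distributions are irrelevant to format
correctness, determinism is not: the same spec and seed always generate a
deep-equal container, and generation leaves the caller's RNG stream
untouched. The corpus emulates the *structure* of real single-cell data,
not its biology: passing tests demonstrate faithful storage and
conversion of every supported type and shape, not that any analysis on
real data is meaningful. Real datasets can additionally contain encodings
outside the registry (awkward/ragged arrays) which this package rejects
explicitly rather than mangling.

Default problem sizes are 25 observations x 12 variables per fixture (19
fixtures) and 13 x 9 matrices for the sparse oracle (100 per orientation
across densities 0, 0.1, 0.5 and 1); format correctness is
size-independent, so the suites run at desk scale.

# Limitations

* Zarr backing and ragged-array encodings are out of scope.
* Backed mode materializes whole slots; sliced on-disk reads are not
  provided.
* Files are written whole; appending or in-place element updates are not
  supported.
* Integer values outside R's 32-bit range decode to doubles (with a
  warning).
* Multimodal containers and direct SCE-to-Seurat conversion are not
  goals; compose through the AnnData container instead.
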