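#' @importClassesFrom Matrix dgCMatrix
#' @exportClass cell_matrix
setClass("cell_matrix", contains = "dgCMatrix",
         representation(modality = "character"))

#' Construct a cell-by-feature count matrix
#'
#' The basic container for raw single-cell counts: a sparse cells x features
#' matrix of non-negative integers, tagged with its modality. Rows are cells,
#' columns are features (genes for RNA, peaks or bins for ATAC). The class
#' extends `dgCMatrix`, so all sparse-matrix operations apply directly.
#'
#' @param values Matrix-like (dense or `Matrix` sparse) of non-negative
#'   integer counts, cells in rows.
#' @param cell_ids Character vector of unique cell identifiers (barcodes).
#' @param feature_ids Character vector of unique feature identifiers.
#' @param modality `"rna"` or `"atac"`.
#'
#' @return A `cell_matrix` object.
#' @export
cell_matrix <- function(values, cell_ids = rownames(values),
                        feature_ids = colnames(values),
                        modality = c("rna", "atac")) {
  modality <- match.arg(modality)
  m <- as(as(as(values, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (nrow(m) < 2) abort("a cell matrix needs at least 2 cells")
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(m)))
  if (is.null(feature_ids)) feature_ids <- paste0("feature_", seq_len(ncol(m)))
  if (anyDuplicated(cell_ids)) abort("duplicate cell ids")
  if (anyDuplicated(feature_ids)) abort("duplicate feature ids")
  if (length(cell_ids) != nrow(m) || length(feature_ids) != ncol(m)) {
    abort("id lengths do not match matrix dimensions")
  }
  x <- m@x
  if (length(x) && (min(x) < 0 || any(x != floor(x)))) {
    abort("counts must be non-negative integers")
  }
  dimnames(m) <- list(as.character(cell_ids), as.character(feature_ids))
  new("cell_matrix", m, modality = modality)
}

setMethod("show", "cell_matrix", function(object) {
  cat(sprintf("<cell_matrix [%s]> %d cells x %d features, %d non-zero\n",
              object@modality, nrow(object), ncol(object), length(object@x)))
})

modality_of <- function(x) {
  if (is(x, "cell_matrix")) x@modality else "rna"
}

# strip the subclass so plain Matrix methods dispatch without surprises
as_dgc <- function(x) as(x, "dgCMatrix")
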