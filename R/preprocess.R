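#' Quality-filter raw single-cell counts
#'
#' Retains cells with strictly more than `minGenes` genes detected and
#' strictly more than `minReads` total reads ("more than" is taken literally:
#' a cell at exactly the boundary is removed). Genes that are zero in every
#' retained cell are dropped. Cell order is preserved.
#'
#' @param counts integer matrix, genes x cells (dense or `dgCMatrix`).
#' @param minGenes minimum genes detected per cell (strict).
#' @param minReads minimum total reads per cell (strict).
#' @param removeGenePatterns character vector of regular expressions; genes
#'   whose symbol matches any pattern are removed before cell filtering.
#'   Defaults target mitochondrial and ribosomal symbols.
#' @return filtered count matrix, with attribute `"removedCells"` holding the
#'   dropped cell names.
#' @export
#' @examples
#' m <- matrix(rpois(30, 5), 6, 5,
#'             dimnames = list(paste0("g", 1:6), paste0("c", 1:5)))
#' filterCells(m, minGenes = 2, minReads = 10)
filterCells <- function(counts, minGenes = 200, minReads = 1000,
                        removeGenePatterns = c("^MT-", "^RP[SL]")) {
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
  if (length(removeGenePatterns)) {
    drop <- Reduce(`|`, lapply(removeGenePatterns, grepl,
                               x = rownames(counts)))
    counts <- counts[!drop, , drop = FALSE]
  }
  genesDetected <- Matrix::colSums(counts > 0)
  totalReads <- Matrix::colSums(counts)
  keep <- genesDetected > minGenes & totalReads > minReads
  if (!any(keep))
    stop("no cells pass QC (minGenes = ", minGenes,
         ", minReads = ", minReads, ")")
  removed <- colnames(counts)[!keep]
  out <- counts[, keep, drop = FALSE]
  out <- out[Matrix::rowSums(out) > 0, , drop = FALSE]
  attr(out, "removedCells") <- removed
  out
}

#' Log2 counts-per-scale normalization
#'
#' Scales each cell to a common total (`scale`, default counts-per-million)
#' and applies `log2(1 + x)`. Monotone within each cell, so within-cell rank
#' order is preserved.
#'
#' @param counts non-negative matrix, genes x cells.
#' @param scale per-cell total after scaling (default `1e6`, CPM).
#' @return numeric matrix of log2-normalized values.
#' @export
normalizeLog2 <- function(counts, scale = 1e6) {
  totals <- Matrix::colSums(counts)
  if (any(totals == 0))
    stop("cells with zero total counts cannot be normalized: ",
         paste(colnames(counts)[totals == 0], collapse = ", "))
  out <- sweep(as.matrix(counts), 2L, totals / scale, "/")
  log2(1 + out)
}

#' Detect a bimodal expression threshold
#'
#' Kernel-density estimate of the value distribution; the threshold is the
#' density minimum between the two highest modes (the "valley"). Degenerate
#' (constant or unimodal) inputs fall back to `fallback`, the conventional
#' 0.2 log2-CPM gate for IFNG positivity.
#'
#' @param values numeric vector, at least 100 values.
#' @param fallback threshold returned when no valley exists (default 0.2).
#' @param bw kernel bandwidth passed to [stats::density()].
#' @return numeric threshold.
#' @export
detectBimodalThreshold <- function(values, fallback = 0.2, bw = "nrd0") {
  if (length(values) < 100)
    stop("need at least 100 values to estimate a bimodal threshold")
  if (stats::sd(values) == 0 || length(unique(values)) < 3L) {
    warning("constant input; returning fallback threshold ", fallback)
    return(fallback)
  }
  d <- stats::density(values, bw = bw)
  y <- d$y
  ## interior local maxima / minima of the KDE grid
  up <- diff(y) > 0
  peaks <- which(c(FALSE, up) & c(!up, FALSE))
  if (y[1] > y[2]) peaks <- c(1L, peaks)
  if (y[length(y)] > y[length(y) - 1]) peaks <- c(peaks, length(y))
  if (length(peaks) < 2L) {
    warning("unimodal density; returning fallback threshold ", fallback)
    return(fallback)
  }
  top2 <- sort(peaks[order(y[peaks], decreasing = TRUE)][1:2])
  valley <- top2[1] + which.min(y[top2[1]:top2[2]]) - 1L
  d$x[valley]
}

#' Binarize expression values
#'
#' Strictly-greater-than comparison: a value exactly at the threshold is
#' negative.
#'
#' @param values numeric vector or matrix.
#' @param threshold finite numeric threshold.
#' @return logical of the same shape.
#' @export
binarize <- function(values, threshold = 0.2) {
  stopifnot(is.finite(threshold) || is.infinite(threshold))
  values > threshold
}

#' Assemble a cell-level container
#'
#' Wraps a log2-normalized expression matrix and per-cell metadata into a
#' [SingleCellExperiment::SingleCellExperiment] with assay `logcounts` and
#' the derived `ifng_positive` gate in `colData`.
#'
#' @param expression numeric matrix, genes x cells, log2-normalized.
#' @param patient character vector of patient ids, one per cell.
#' @param tissue `"tumor"` or `"normal"` per cell.
#' @param subtype `"MSI"` or `"MSS"` per cell.
#' @param subpopulation optional free-text label per cell.
#' @param ifngThreshold gate applied to the `IFNG` row (default 0.2).
#' @return a `SingleCellExperiment`.
#' @export
makeCellTable <- function(expression, patient, tissue, subtype,
                          subpopulation = NULL, ifngThreshold = 0.2) {
  stopifnot(!is.null(colnames(expression)), !is.null(rownames(expression)))
  if (anyDuplicated(colnames(expression)))
    stop("duplicate cell ids")
  if (any(expression < 0))
    stop("log2-normalized expression must be non-negative")
  stopifnot(length(patient) == ncol(expression),
            length(tissue) == ncol(expression),
            all(tissue %in% c("tumor", "normal")))
  cd <- S4Vectors::DataFrame(
    patient_id = patient,
    tissue = tissue,
    subtype = subtype,
    row.names = colnames(expression)
  )
  if (!is.null(subpopulation)) cd$subpopulation <- subpopulation
  if ("IFNG" %in% rownames(expression)) {
    cd$ifng_positive <- as.logical(binarize(expression["IFNG", ],
                                            ifngThreshold))
  }
  SingleCellExperiment::SingleCellExperiment(
    assays = list(logcounts = expression), colData = cd)
}
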