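## Rank (Spearman) correlation across columns of a cells x genes matrix,
## average ranks on ties. Returns the genes x genes correlation matrix.
.rankCor <- function(mat) {
  stats::cor(apply(mat, 2L, rank), method = "pearson")
}

#' Discover co-expression signaling modules
#'
#' Partitions genes into co-expression modules among (typically IFNG+) cells:
#' a Spearman correlation matrix over genes is computed, genes are compared by
#' the Euclidean distance between their correlation-profile rows, and the
#' complete-linkage hierarchical tree is cut into `k` groups. Deterministic
#' given the input; invariant to cell order and (up to label permutation) to
#' gene order.
#'
#' @param cells a `SingleCellExperiment` (assay `logcounts`) or a genes x
#'   cells matrix.
#' @param genes gene symbols to partition (default: the 39-gene universe
#'   intersected with measured genes).
#' @param k number of modules to cut (default 5).
#' @param linkage linkage method for [stats::hclust()] (default
#'   `"complete"`).
#' @return named integer vector, gene -> module id in `1..k`.
#' @export
discoverModules <- function(cells, genes = NULL, k = 5,
                            linkage = "complete") {
  expr <- .asExpression(cells)
  if (is.null(genes)) genes <- intersect(tumorReactiveUniverse(),
                                         rownames(expr))
  missing <- setdiff(genes, rownames(expr))
  if (length(missing))
    stop("genes not measured: ", paste(missing, collapse = ", "))
  if (k > length(genes)) stop("k exceeds the number of genes")
  x <- t(expr[genes, , drop = FALSE])   # cells x genes
  sds <- apply(x, 2L, stats::sd)
  flat <- sds == 0
  if (all(!flat) && length(genes) < 2L)
    stop("need at least 2 genes with nonzero variance")
  active <- genes[!flat]
  if (length(active) < 2L) stop("fewer than 2 genes with nonzero variance")
  rc <- .rankCor(x[, active, drop = FALSE])
  hc <- stats::hclust(stats::dist(rc), method = linkage)
  part <- stats::cutree(hc, k = min(k, length(active)))
  if (any(flat)) {
    warning("zero-variance genes assigned by nearest-module fallback: ",
            paste(genes[flat], collapse = ", "))
    ## nearest module = module of the gene with the closest mean expression
    mExpr <- colMeans(x)
    for (g in genes[flat]) {
      nearest <- active[which.min(abs(mExpr[active] - mExpr[g]))]
      part[g] <- part[nearest]
    }
    part <- part[genes]
  }
  part
}

#' Activation map of binarized module expression
#'
#' Mean binarized expression per (cell group, module): entry `(g, m)` is the
#' mean over cells in group `g` and genes in module `m` of
#' `expression > threshold`. Values lie in `[0, 1]`; raising the threshold
#' never increases an entry. Empty groups yield `NA` rows.
#'
#' @param cells `SingleCellExperiment` or genes x cells matrix.
#' @param modules a [SignalingModuleSet-class] or named list of gene sets.
#' @param groups factor/character of length `ncol(cells)` (e.g.
#'   subpopulation or patient).
#' @param threshold binarization gate (default 0.2).
#' @return numeric matrix, groups x modules.
#' @export
activationMap <- function(cells, modules, groups, threshold = 0.2) {
  expr <- .asExpression(cells)
  if (is(modules, "SignalingModuleSet")) modules <- moduleGenes(modules)
  stopifnot(length(groups) == ncol(expr))
  if (!is.factor(groups)) groups <- factor(groups)
  if (!nlevels(groups)) stop("groups must be non-empty")
  out <- matrix(NA_real_, nlevels(groups), length(modules),
                dimnames = list(levels(groups), names(modules)))
  bin <- binarize(expr, threshold)
  for (m in names(modules)) {
    g <- intersect(modules[[m]], rownames(expr))
    if (!length(g)) next
    sub <- bin[g, , drop = FALSE]
    for (lv in levels(groups)) {
      idx <- which(groups == lv)
      out[lv, m] <- if (length(idx)) mean(sub[, idx]) else NA_real_
    }
  }
  out
}

#' Per-cell binarized signature score
#'
#' Mean of binarized expression over the signature genes measured in the
#' data (the NeoTCR-style score). Genes absent from the matrix are reported
#' via message; an empty intersection is an error naming the missing genes.
#'
#' @inheritParams activationMap
#' @param geneSet character vector of signature genes.
#' @return named numeric vector in `[0, 1]`, one score per cell.
#' @export
scoreSignatureBinarized <- function(cells, geneSet, threshold = 0.2) {
  expr <- .asExpression(cells)
  found <- intersect(geneSet, rownames(expr))
  missing <- setdiff(geneSet, rownames(expr))
  if (!length(found))
    stop("no signature genes measured; missing: ",
         paste(missing, collapse = ", "))
  if (length(missing))
    message("signature genes not measured (ignored): ",
            paste(missing, collapse = ", "))
  colMeans(binarize(expr[found, , drop = FALSE], threshold))
}

#' Metagene: per-sample mean expression over a gene set
#'
#' @param expression genes x samples matrix (single-cell or bulk) or a
#'   `SingleCellExperiment`.
#' @param geneSet character vector of genes.
#' @return named numeric vector, one value per sample.
#' @export
metagene <- function(expression, geneSet) {
  expr <- .asExpression(expression)
  found <- intersect(geneSet, rownames(expr))
  if (!length(found))
    stop("no metagene genes measured; missing: ",
         paste(setdiff(geneSet, rownames(expr)), collapse = ", "))
  colMeans(expr[found, , drop = FALSE])
}

#' Module overlap: presence/absence and Jaccard similarity
#'
#' For module sets A, B: `J(A, B) = |A intersect B| / |A union B|`. Two empty
#' sets have similarity 1; an empty vs a non-empty set has 0.
#'
#' @param moduleSets a [SignalingModuleSet-class] or named list of gene sets
#'   (at least 2).
#' @return list with `presence` (modules x genes 0/1 matrix over the union)
#'   and `jaccard` (symmetric similarity matrix with unit diagonal).
#' @export
moduleOverlap <- function(moduleSets) {
  if (is(moduleSets, "SignalingModuleSet"))
    moduleSets <- moduleGenes(moduleSets)
  if (length(moduleSets) < 2L) stop("need at least 2 module sets")
  universe <- sort(unique(unlist(moduleSets)))
  presence <- t(vapply(moduleSets, function(g)
    as.integer(universe %in% g), integer(length(universe))))
  colnames(presence) <- universe
  n <- length(moduleSets)
  jac <- matrix(1, n, n, dimnames = list(names(moduleSets),
                                         names(moduleSets)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- moduleSets[[i]]; b <- moduleSets[[j]]
    u <- length(union(a, b))
    jac[i, j] <- if (u == 0) 1 else length(intersect(a, b)) / u
  }
  list(presence = presence, jaccard = jac)
}

## Coerce SingleCellExperiment / SummarizedExperiment / matrix to a plain
## genes x samples matrix.
.asExpression <- function(x) {
  if (is(x, "SummarizedExperiment")) {
    nm <- SummarizedExperiment::assayNames(x)
    a <- if ("logcounts" %in% nm) "logcounts" else nm[1L]
    return(as.matrix(SummarizedExperiment::assay(x, a)))
  }
  as.matrix(x)
}
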