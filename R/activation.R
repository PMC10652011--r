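#' Score cells on the TCR-activation and bystander-activation axes
#'
#' Each cell's expression over the signature genes is rank-correlated
#' (Spearman) with the TCR-activation centroid profile and with the
#' bystander-activation centroid profile. Because scores are rank-based they
#' are invariant to monotone per-cell transformations of expression. Cells
#' that are constant over the signature genes receive `NA` with a warning.
#'
#' @param cells `SingleCellExperiment` or genes x cells matrix.
#' @param centroids data.frame with columns `gene`, `tcr_mean`,
#'   `bystander_mean`: the average expression of the two reference activation
#'   states over the signature genes.
#' @return data.frame with columns `cell_id`, `r_tcr`, `r_bys`.
#' @export
scoreActivation <- function(cells, centroids) {
  expr <- .asExpression(cells)
  stopifnot(all(c("gene", "tcr_mean", "bystander_mean") %in%
                  names(centroids)))
  genes <- intersect(centroids$gene, rownames(expr))
  if (length(genes) < 3L)
    stop("centroids and cells share fewer than 3 genes")
  cen <- centroids[match(genes, centroids$gene), ]
  sub <- expr[genes, , drop = FALSE]
  flat <- apply(sub, 2L, function(v) stats::sd(v) == 0)
  if (any(flat))
    warning(sum(flat), " cell(s) constant over signature genes; NA scores")
  corTo <- function(target) {
    r <- suppressWarnings(
      stats::cor(sub, target, method = "spearman")[, 1L])
    r[flat] <- NA_real_
    r
  }
  data.frame(
    cell_id = colnames(expr),
    r_tcr = corTo(cen$tcr_mean),
    r_bys = corTo(cen$bystander_mean),
    row.names = NULL
  )
}

#' Directionality between TCR and bystander activation
#'
#' `median(r_tcr) - median(r_bys)`; an absolute difference below
#' `nonDirectionalBand` (default 0.2) is classified non-directional.
#' Antisymmetric under swapping the two score vectors.
#'
#' @param rTcr,rBys numeric score vectors (NAs dropped).
#' @param nonDirectionalBand half-width of the non-directional band.
#' @return numeric difference with attribute `"direction"`, one of
#'   `"TCR-directed"`, `"bystander-directed"`, `"non-directional"`.
#' @export
directionality <- function(rTcr, rBys, nonDirectionalBand = 0.2) {
  rTcr <- rTcr[!is.na(rTcr)]; rBys <- rBys[!is.na(rBys)]
  if (!length(rTcr) || !length(rBys)) stop("empty score vector")
  d <- stats::median(rTcr) - stats::median(rBys)
  cls <- if (abs(d) < nonDirectionalBand) "non-directional"
         else if (d > 0) "TCR-directed" else "bystander-directed"
  structure(d, class = NULL, direction = cls)
}

#' Reference center from normal-tissue cells
#'
#' Per-axis mean of the activation scores of reference (normal-adjacent
#' tissue) cells; the "x" against which tumor cells are partitioned into
#' quadrants.
#'
#' @param scores data.frame from [scoreActivation()] on reference cells.
#' @param fun summary function (default [mean()]; the population center
#'   convention).
#' @return list with `center_tcr`, `center_bys`, `source`.
#' @export
referenceCenter <- function(scores, fun = mean) {
  list(center_tcr = fun(scores$r_tcr, na.rm = TRUE),
       center_bys = fun(scores$r_bys, na.rm = TRUE),
       source = "reference cells (per-axis mean)")
}

#' Partition activation scores into quadrants
#'
#' High/Low on each axis by strict comparison to the reference center: a cell
#' exactly at the center is Low on that axis. Quadrant labels combine the TCR
#' axis first (`H`/`L`) then the bystander axis, e.g. `"HL"` =
#' TCR-high/bystander-low.
#'
#' @param scores data.frame from [scoreActivation()].
#' @param reference list from [referenceCenter()].
#' @return list with `quadrant` (character per cell) and `counts` (named
#'   2x2-table flattened over `LL, LH, HL, HH`).
#' @export
quadrantPartition <- function(scores, reference) {
  stopifnot(is.finite(reference$center_tcr),
            is.finite(reference$center_bys))
  hiT <- scores$r_tcr > reference$center_tcr
  hiB <- scores$r_bys > reference$center_bys
  q <- paste0(ifelse(hiT, "H", "L"), ifelse(hiB, "H", "L"))
  q[is.na(scores$r_tcr) | is.na(scores$r_bys)] <- NA_character_
  counts <- vapply(c("LL", "LH", "HL", "HH"),
                   function(k) sum(q == k, na.rm = TRUE), integer(1))
  list(quadrant = q, counts = counts)
}

#' Welch's unequal-variance t test
#'
#' Two-sided Welch t test (Welch-Satterthwaite degrees of freedom), as used
#' for quadrant cell-count comparisons.
#'
#' @param a,b numeric vectors, each with at least 2 finite values.
#' @return list with `t`, `df`, `p`.
#' @export
welchTest <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    stop("zero variance in both groups")
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}
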