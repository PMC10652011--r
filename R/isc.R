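#' Single-cell patient stratification on module means
#'
#' Complete-linkage Euclidean hierarchical clustering of patients on their
#' per-patient module-mean vectors, cut at `nClusters` (2 for MSI, 3 for MSS
#' in the canonical configuration).
#'
#' @param moduleMeans patients x modules numeric matrix (e.g. a per-patient
#'   [activationMap()]).
#' @param nClusters number of clusters to cut.
#' @return named integer cluster ids per patient.
#' @export
stratifyPatientsSc <- function(moduleMeans, nClusters) {
  stopifnot(is.matrix(moduleMeans), all(is.finite(moduleMeans)))
  if (nClusters > nrow(moduleMeans))
    stop("nClusters exceeds the number of patients")
  hc <- stats::hclust(stats::dist(moduleMeans, method = "euclidean"),
                      method = "complete")
  stats::cutree(hc, k = nClusters)
}

#' L1-normalize expression per patient
#'
#' Divides each patient's (column's) gene vector by its absolute sum so
#' columns sum to 1. Idempotent; zero-sum patients are an error.
#'
#' @param expression non-negative genes x patients matrix.
#' @return normalized matrix of the same shape.
#' @export
l1Normalize <- function(expression) {
  expression <- as.matrix(expression)
  if (any(expression < 0)) stop("expression must be non-negative")
  s <- colSums(abs(expression))
  if (any(s == 0))
    stop("zero-sum patients: ",
         paste(colnames(expression)[s == 0], collapse = ", "))
  sweep(expression, 2L, s, "/")
}

#' Per-signature patient distance matrices
#'
#' For each signaling module, `D(i, j) = 1 - Spearman(x_i, x_j)` over the
#' module's genes, averaged over modules into the manifold used for ISC
#' clustering. Modules with fewer than `minGenes` measured genes are
#' skipped with a warning; constant patient vectors yield `NA` entries.
#'
#' @param expression genes x patients matrix (typically L1-normalized).
#' @param modules [SignalingModuleSet-class] or named list of gene sets.
#' @param minGenes minimum measured genes per module (default 3).
#' @return a [PatientDistanceMatrix-class].
#' @export
patientDistance <- function(expression, modules, minGenes = 3) {
  expression <- as.matrix(expression)
  if (is(modules, "SignalingModuleSet")) modules <- moduleGenes(modules)
  patients <- colnames(expression)
  per <- list()
  for (m in names(modules)) {
    g <- intersect(modules[[m]], rownames(expression))
    if (length(g) < minGenes) {
      warning("module ", m, " has fewer than ", minGenes,
              " measured genes; skipped")
      next
    }
    sub <- expression[g, , drop = FALSE]
    flat <- apply(sub, 2L, function(v) stats::sd(v) == 0)
    if (any(flat))
      warning("constant patient vectors over module ", m, ": ",
              paste(patients[flat], collapse = ", "))
    rho <- suppressWarnings(stats::cor(sub, method = "spearman"))
    d <- 1 - rho
    d[flat, ] <- NA; d[, flat] <- NA
    diag(d) <- 0
    per[[m]] <- d
  }
  if (!length(per)) stop("no module with enough measured genes")
  avg <- Reduce(`+`, per) / length(per)
  new("PatientDistanceMatrix", patients = patients, perSignature = per,
      averaged = avg)
}

#' Agglomerative ISC clustering on the averaged distance
#'
#' Average-linkage agglomerative clustering on the precomputed averaged
#' patient distance. `k` is chosen in `2..maxGroups` by mean silhouette
#' width on the averaged distance unless `k` is fixed. Deterministic.
#'
#' @param dist a [PatientDistanceMatrix-class] or symmetric matrix.
#' @param maxGroups maximum number of groups (default 5).
#' @param k optional fixed number of groups, overriding silhouette
#'   selection.
#' @return list with `labels` (named integer), `k`, `silhouette` (named
#'   numeric over candidate k, `NA` when `k` was fixed).
#' @export
iscCluster <- function(dist, maxGroups = 5, k = NULL) {
  d <- if (is(dist, "PatientDistanceMatrix")) averagedDistance(dist)
       else as.matrix(dist)
  if (nrow(d) < 2L) stop("need at least 2 patients")
  if (max(d, na.rm = TRUE) - min(d, na.rm = TRUE) < 1e-12) {
    warning("degenerate all-equal distances; one group returned")
    return(list(labels = stats::setNames(rep(1L, nrow(d)), rownames(d)),
                k = 1L, silhouette = NA))
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  if (!is.null(k)) {
    lab <- stats::cutree(hc, k = k)
    return(list(labels = lab, k = as.integer(k), silhouette = NA))
  }
  ks <- 2:min(maxGroups, nrow(d) - 1L)
  sil <- vapply(ks, function(kk) {
    lab <- stats::cutree(hc, k = kk)
    mean(cluster::silhouette(lab, dmatrix = d)[, "sil_width"])
  }, numeric(1))
  names(sil) <- ks
  best <- ks[which.max(sil)]
  list(labels = stats::cutree(hc, k = best), k = best, silhouette = sil)
}

#' Name ISC clusters from module metagene profiles
#'
#' MSI: the cluster with the higher mean stem-like-progenitor metagene is
#' `ISC1a`, the other `ISC1b`. MSS: clusters are ranked by overall mean
#' module metagene; the split between the inflamed `ISC2` side and the
#' immune-silent `ISC3` side falls at the largest gap in overall signal,
#' with at most 3 ISC2 and at most 2 ISC3 clusters; within each side labels
#' descend with signal (`ISC2a >= ISC2b >= ISC2c`, `ISC3a >= ISC3b`). Ties
#' break on the long-term-immunosurveillance metagene, then lexicographic
#' cluster id.
#'
#' @param clusters named integer vector, patient -> cluster id.
#' @param moduleMetagenes patients x modules matrix of metagene values
#'   (columns named by module; a stem-like column is required for MSI).
#' @param subtype `"MSI"` or `"MSS"`.
#' @return an [IscLabeling-class].
#' @export
labelIsc <- function(clusters, moduleMetagenes, subtype = c("MSI", "MSS")) {
  subtype <- match.arg(subtype)
  stopifnot(!is.null(names(clusters)),
            all(names(clusters) %in% rownames(moduleMetagenes)))
  mm <- moduleMetagenes[names(clusters), , drop = FALSE]
  ids <- sort(unique(clusters))
  profile <- t(vapply(ids, function(cl)
    colMeans(mm[clusters == cl, , drop = FALSE]), numeric(ncol(mm))))
  rownames(profile) <- as.character(ids)
  colnames(profile) <- colnames(mm)
  lti <- grep("long_term_immunosurveillance", colnames(profile))
  tieKey <- if (length(lti)) profile[, lti[1L]] else rep(0, nrow(profile))
  overall <- rowMeans(profile)
  ord <- order(-overall, -tieKey, rownames(profile))
  if (subtype == "MSI") {
    if (length(ids) != 2L)
      stop("MSI naming expects exactly 2 clusters, got ", length(ids))
    stemCol <- grep("stem_like", colnames(profile))
    if (!length(stemCol))
      stop("moduleMetagenes needs a stem-like progenitor column")
    stem <- profile[, stemCol[1L]]
    ordStem <- order(-stem, -tieKey, rownames(profile))
    names <- character(2L)
    names[ordStem] <- c("ISC1a", "ISC1b")
  } else {
    nc <- length(ids)
    if (nc < 2L || nc > 5L)
      stop("MSS naming expects 2..5 clusters, got ", nc)
    sorted <- overall[ord]
    gaps <- -diff(sorted)            # drop between consecutive ranks
    ## ISC2 side takes 1..split, ISC3 side the rest; bounds: <=3 vs <=2
    lo <- max(1L, nc - 2L); hi <- min(3L, nc - 1L)
    cand <- lo:hi
    split <- cand[which.max(gaps[cand])]
    names <- character(nc)
    names[ord[seq_len(split)]] <- paste0("ISC2", letters[seq_len(split)])
    names[ord[(split + 1L):nc]] <-
      paste0("ISC3", letters[seq_len(nc - split)])
  }
  lab <- stats::setNames(names[match(clusters, ids)], names(clusters))
  new("IscLabeling", subtype = subtype, labels = lab,
      clusters = stats::setNames(as.integer(clusters), names(clusters)),
      profile = profile)
}

#' Cross-validated importance feature selection
#'
#' Repeated stratified k-fold cross-validation: an impurity-importance
#' random forest is trained per fold and repeat, per-model importances are
#' normalized to sum 1 and averaged, and genes with mean importance strictly
#' above `threshold` are retained. Deterministic under the given seed.
#'
#' @param x samples x genes numeric matrix.
#' @param y factor of class labels.
#' @param threshold mean-importance retention threshold (default 0.001).
#' @param folds number of CV folds (default 5).
#' @param repeats number of CV repeats (default 2).
#' @param nTrees trees per fold model (default 500).
#' @param seed integer seed.
#' @return character vector of retained genes, with attribute
#'   `"importance"` (named mean importances, descending).
#' @export
selectFeatures <- function(x, y, threshold = 0.001, folds = 5, repeats = 2,
                           nTrees = 500, seed = 12) {
  x <- as.matrix(x); y <- droplevels(factor(y))
  if (min(table(y)) < folds)
    stop("need at least `folds` samples per class")
  rng <- .seedStream(seed, repeats)
  imp <- matrix(0, ncol(x), folds * repeats,
                dimnames = list(colnames(x), NULL))
  col <- 0L
  for (r in seq_len(repeats)) {
    set.seed(rng[r])
    foldId <- unsplit(lapply(split(seq_along(y), y), function(idx)
      sample(rep_len(seq_len(folds), length(idx)))), y)
    for (f in seq_len(folds)) {
      col <- col + 1L
      tr <- foldId != f
      fit <- .fitForest(x[tr, , drop = FALSE], y[tr], nTrees = nTrees,
                        seed = rng[r] + f, probability = FALSE)
      v <- fit$variable.importance
      if (sum(v) > 0) v <- v / sum(v)
      imp[names(v), col] <- v
    }
  }
  meanImp <- sort(rowMeans(imp), decreasing = TRUE)
  keep <- names(meanImp)[meanImp > threshold]
  if (!length(keep))
    stop("no gene passes the importance threshold ", threshold,
         "; consider lowering it")
  structure(keep, importance = meanImp)
}

.fitForest <- function(x, y, nTrees, seed, probability = TRUE) {
  df <- data.frame(x, check.names = FALSE)
  df$.label <- y
  w <- as.numeric(length(y) / (nlevels(y) * table(y)))  # balanced
  ranger::ranger(
    dependent.variable.name = ".label", data = df,
    num.trees = nTrees, importance = "impurity",
    probability = probability, class.weights = w,
    seed = seed, num.threads = 1L)
}

#' Train the ISC label-transfer classifier
#'
#' Balanced-class-weight probability random forest on the selected genes
#' (defaults mirror the canonical configuration: seed 12, balanced class
#' weights; `nTrees` defaults to 5000).
#'
#' @param x samples x genes matrix.
#' @param y factor of ISC labels.
#' @param genes genes to train on (default: all columns of `x`; typically
#'   the output of [selectFeatures()]).
#' @param nTrees number of trees (default 5000).
#' @param seed integer seed (default 12).
#' @return an [IscClassifier-class].
#' @export
trainIscClassifier <- function(x, y, genes = colnames(x), nTrees = 5000,
                               seed = 12) {
  x <- as.matrix(x); y <- droplevels(factor(y))
  if (nlevels(y) < 2L) stop("need at least 2 classes")
  missing <- setdiff(genes, colnames(x))
  if (length(missing))
    stop("selected genes absent from training data: ",
         paste(missing, collapse = ", "))
  fit <- .fitForest(x[, genes, drop = FALSE], y, nTrees = nTrees,
                    seed = seed, probability = TRUE)
  new("IscClassifier", selectedGenes = genes, forest = fit,
      classLevels = levels(y),
      training = list(nTrees = nTrees, seed = seed, n = nrow(x)))
}

#' Predict ISC labels and probabilities
#'
#' Missing selected genes in the new data are imputed as 0 with a warning.
#' Probabilities sum to 1 per sample; the argmax label is reported.
#'
#' @param model an [IscClassifier-class].
#' @param x samples x genes matrix.
#' @return data.frame with `label` plus one probability column per class.
#' @export
predictIsc <- function(model, x) {
  x <- as.matrix(x)
  miss <- setdiff(selectedGenes(model), colnames(x))
  if (length(miss)) {
    warning("genes missing from new data imputed as 0: ",
            paste(miss, collapse = ", "))
    x <- cbind(x, matrix(0, nrow(x), length(miss),
                         dimnames = list(rownames(x), miss)))
  }
  newdata <- data.frame(x[, selectedGenes(model), drop = FALSE],
                        check.names = FALSE)
  pr <- stats::predict(model@forest, data = newdata,
                       num.threads = 1L)$predictions
  colnames(pr) <- colnames(pr)  # ranger keeps class names
  lab <- colnames(pr)[max.col(pr, ties.method = "first")]
  out <- data.frame(label = lab, pr, check.names = FALSE)
  rownames(out) <- rownames(x)
  out
}

#' Bulk TCR-to-bystander directionality ratio
#'
#' Per-patient ratio of the TCR-activation signature metagene to the
#' bystander-activation signature metagene; zero denominators give `NA`.
#'
#' @param expression genes x patients matrix.
#' @param tcrSignature,bystanderSignature character gene sets.
#' @return named numeric vector per patient.
#' @export
directionalityRatioBulk <- function(expression, tcrSignature,
                                    bystanderSignature) {
  num <- metagene(expression, tcrSignature)
  den <- metagene(expression, bystanderSignature)
  out <- num / den
  out[den == 0] <- NA_real_
  out
}
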