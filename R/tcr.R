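.AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.pkgCache <- new.env(parent = emptyenv())

.blosum62 <- function() {
  if (is.null(.pkgCache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkgCache$BLOSUM62 <- e$BLOSUM62
  }
  .pkgCache$BLOSUM62
}

.checkAa <- function(x) {
  if (!length(x) || any(!nzchar(x)))
    stop("empty amino-acid sequence")
  bad <- grepl(paste0("[^", paste(.AA, collapse = ""), "]"), x)
  if (any(bad))
    stop("invalid amino-acid alphabet in: ",
         paste(unique(x[bad]), collapse = ", "))
  invisible(x)
}

#' BLOSUM62 local alignment score
#'
#' Best local (Smith-Waterman) alignment score under BLOSUM62 with the
#' aligner convention that the first gapped residue costs the open penalty
#' (4) and each further residue the extension penalty (4), i.e. a gap of
#' length L costs `4 + 4*(L-1)`. Symmetric in its arguments.
#'
#' @param a,b amino-acid strings (vectorized; recycled to common length).
#' @return numeric score(s).
#' @export
#' @examples
#' localAlign("CASSL", "CASSL")  # 9+4+4+4+4 = 25
localAlign <- function(a, b) {
  .checkAa(a); .checkAa(b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  as.numeric(Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(a), Biostrings::AAStringSet(b),
    type = "local", substitutionMatrix = .blosum62(),
    gapOpening = 0, gapExtension = 4, scoreOnly = TRUE))
}

#' Alignment identity fraction
#'
#' `localAlign(query, target) / localAlign(target, target)`, clipped to
#' `[0, 1]`: the query score as a proportion of the target's known maximum
#' (self) score. Identical sequences score exactly 1.
#'
#' @param query,target amino-acid strings (vectorized).
#' @return numeric in `[0, 1]`.
#' @export
identityFraction <- function(query, target) {
  s <- localAlign(query, target)
  smax <- localAlign(target, target)
  pmin(1, pmax(0, s / smax))
}

#' MAIT TCR score for a cell
#'
#' For each known invariant alpha/beta pair the product of the alpha-chain
#' and beta-chain identity fractions is computed; the cell's score is the
#' maximum over known pairs. A cell carrying an exact known pair scores 1.
#'
#' @param alpha,beta the cell's productive CDR3 amino-acid sequences (one or
#'   more per chain).
#' @param knownPairs data.frame with columns `alpha_aa`, `beta_aa`
#'   (default [maitReferencePairs()]).
#' @return numeric score in `[0, 1]`, or `NA` if a chain is missing.
#' @export
maitScore <- function(alpha, beta, knownPairs = maitReferencePairs()) {
  if (!length(alpha) || !length(beta)) return(NA_real_)
  best <- 0
  for (i in seq_len(nrow(knownPairs))) {
    fa <- max(identityFraction(alpha, knownPairs$alpha_aa[i]))
    fb <- max(identityFraction(beta, knownPairs$beta_aa[i]))
    best <- max(best, fa * fb)
  }
  best
}

#' Call tumor-exclusive TCRs against a normal-tissue repertoire
#'
#' A tumor beta-chain CDR3 is exclusive when its best identity fraction
#' against every normal-tissue beta chain is strictly below `threshold`
#' (default 0.80); a fraction of exactly 0.80 is not exclusive.
#'
#' @param tumorBeta character vector of tumor beta-chain CDR3 aa sequences.
#' @param normalBeta character vector of normal-tissue beta-chain CDR3 aa
#'   sequences.
#' @param threshold exclusivity threshold on the identity fraction.
#' @return logical per tumor sequence, with attribute `"maxIdentity"`.
#' @export
callExclusive <- function(tumorBeta, normalBeta, threshold = 0.80) {
  .checkAa(tumorBeta)
  if (!length(normalBeta)) {
    warning("empty normal repertoire; all tumor TCRs called exclusive")
    return(structure(rep(TRUE, length(tumorBeta)),
                     maxIdentity = rep(0, length(tumorBeta))))
  }
  .checkAa(normalBeta)
  normalBeta <- unique(normalBeta)
  best <- vapply(tumorBeta, function(q)
    max(identityFraction(q, normalBeta)), numeric(1))
  structure(unname(best < threshold), maxIdentity = unname(best))
}

#' Define clonotypes from productive rearrangements
#'
#' Cells sharing identical CDR3 nucleotide sequences on all their productive
#' chains share a clonotype. Ids are content hashes of the sorted
#' `locus:junction` strings, so they are stable across runs and record
#' orderings. Cells with a single recovered chain form single-chain
#' clonotypes, flagged in the output.
#'
#' @param records AIRR-style data.frame with columns `cell_id`, `locus`,
#'   `junction`, `productive` (see [readAirr()]).
#' @return data.frame with one row per cell: `cell_id`, `clonotype_id`,
#'   `n_chains`, `single_chain`.
#' @export
defineClonotypes <- function(records) {
  rec <- records[records$productive, , drop = FALSE]
  if (!nrow(rec)) stop("no productive records")
  keys <- vapply(split(rec, rec$cell_id), function(d) {
    paste(sort(paste0(d$locus, ":", d$junction)), collapse = ";")
  }, character(1))
  ids <- paste0("ct_", substr(vapply(keys, .stableHash, character(1)), 1, 12))
  nch <- vapply(split(rec, rec$cell_id), nrow, integer(1))
  data.frame(cell_id = names(keys), clonotype_id = unname(ids),
             n_chains = unname(nch), single_chain = unname(nch) == 1L,
             row.names = NULL)
}

## deterministic content hash without extra dependencies: position-weighted
## polynomial over the raw bytes, reported in hex
.stableHash <- function(s) {
  v <- as.integer(charToRaw(s))
  h <- c(17L, 19L, 23L, 29L)
  for (i in seq_along(v)) {
    j <- (i - 1L) %% 4L + 1L
    h[j] <- (h[j] * 31L + v[i] * i) %% 1048573L
  }
  paste(sprintf("%05x", h), collapse = "")
}

#' Alignment distance between CDR3 sequences
#'
#' `d(a, b) = min(selfScore(a), selfScore(b)) - localAlign(a, b)`: zero for
#' identical sequences, growing as the pair diverges. This symmetric form is
#' the package's pluggable clonotype-cluster distance.
#'
#' @param a,b amino-acid strings (vectorized).
#' @return numeric distance(s), `>= 0` on ordinary sequences.
#' @export
alignmentDistance <- function(a, b) {
  pmin(localAlign(a, a), localAlign(b, b)) - localAlign(a, b)
}

#' Cluster clonotypes by CDR3 similarity
#'
#' Connects clonotypes whose representative CDR3 aa sequences lie within
#' alignment distance `cutoff` (default 15) and returns connected components
#' as clonotype clusters. Components are computed over unique sequences, so
#' the result is invariant to record order.
#'
#' @param cdr3 character vector of CDR3 aa sequences (one per clonotype).
#' @param cutoff distance cutoff for connecting two clonotypes.
#' @return integer cluster ids aligned with `cdr3` (identical sequences get
#'   identical ids; ids are ordered by first appearance of the sorted unique
#'   sequences).
#' @export
clusterClonotypes <- function(cdr3, cutoff = 15) {
  .checkAa(cdr3)
  uniq <- sort(unique(cdr3))
  n <- length(uniq)
  if (n == 1L) return(rep(1L, length(cdr3)))
  self <- localAlign(uniq, uniq)
  adj <- vector("list", n)
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    d <- pmin(self[i], self[js]) - localAlign(rep(uniq[i], length(js)),
                                              uniq[js])
    hit <- js[d <= cutoff]
    adj[[i]] <- c(adj[[i]], hit)
    for (j in hit) adj[[j]] <- c(adj[[j]], i)
  }
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i]) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (comp[v]) next
      comp[v] <- cur
      queue <- c(queue, adj[[v]][comp[adj[[v]]] == 0L])
    }
  }
  comp[match(cdr3, uniq)]
}

#' Annotate clonotypes with predicted epitope specificities
#'
#' Each clonotype's CDR3 is matched against the epitope reference within
#' alignment distance `cutoff`; the annotation is the most frequent
#' `(epitope, organism)` among the hits ("most-frequent" strategy). A tie
#' between distinct top pairs yields `"ambiguous"`; no hit yields
#' `"Unknown"`. The family is carried from the winning reference rows;
#' clonotypes flagged exclusive override to family `"exclusive"`.
#'
#' @param cdr3 character vector of clonotype CDR3 aa sequences.
#' @param reference data.frame with columns `junction_aa`, `epitope`,
#'   `organism`, `family` (and optionally `locus`).
#' @param locus optional chain per clonotype; when both it and a reference
#'   `locus` column are present, matching is chain-specific.
#' @param exclusive optional logical per clonotype from [callExclusive()].
#' @param cutoff alignment-distance cutoff (default 15).
#' @return data.frame with `cdr3`, `epitope`, `organism`, `family`.
#' @export
annotateEpitopes <- function(cdr3, reference, locus = NULL,
                             exclusive = NULL, cutoff = 15) {
  stopifnot(nrow(reference) > 0L)
  .checkAa(cdr3)
  out <- data.frame(cdr3 = cdr3, epitope = "Unknown", organism = "Unknown",
                    family = "Unknown", stringsAsFactors = FALSE)
  chainSpecific <- !is.null(locus) && "locus" %in% names(reference)
  refSelf <- localAlign(reference$junction_aa, reference$junction_aa)
  uniq <- unique(cdr3)
  for (q in uniq) {
    ref <- reference
    selfScores <- refSelf
    if (chainSpecific) {
      keep <- reference$locus == locus[match(q, cdr3)]
      ref <- reference[keep, , drop = FALSE]
      selfScores <- refSelf[keep]
      if (!nrow(ref)) next
    }
    qSelf <- localAlign(q, q)
    d <- pmin(qSelf, selfScores) -
      localAlign(rep(q, nrow(ref)), ref$junction_aa)
    hits <- ref[d <= cutoff, , drop = FALSE]
    idx <- which(cdr3 == q)
    if (!nrow(hits)) next
    key <- paste(hits$epitope, hits$organism, sep = "\r")
    tab <- sort(table(key), decreasing = TRUE)
    if (length(tab) > 1L && tab[1L] == tab[2L]) {
      out$epitope[idx] <- "ambiguous"
      out$organism[idx] <- "ambiguous"
      out$family[idx] <- "ambiguous"
    } else {
      win <- strsplit(names(tab)[1L], "\r", fixed = TRUE)[[1L]]
      out$epitope[idx] <- win[1L]
      out$organism[idx] <- win[2L]
      out$family[idx] <- hits$family[match(names(tab)[1L], key)]
    }
  }
  if (!is.null(exclusive)) {
    out$family[exclusive] <- "exclusive"
    out$epitope[exclusive] <- "Unknown"
    out$organism[exclusive] <- "tumor-exclusive"
  }
  out
}

#' Clonal expansion counts
#'
#' Number of cells per clonotype, optionally stratified; stratified tables
#' always sum back to the unstratified counts.
#'
#' @param assignment data.frame from [defineClonotypes()] (columns `cell_id`,
#'   `clonotype_id`).
#' @param stratifyBy optional named list of per-cell factors (each of length
#'   `nrow(assignment)`), e.g. IFNG status or epitope family.
#' @return data.frame of counts per clonotype (and strata when requested).
#' @export
clonalExpansion <- function(assignment, stratifyBy = NULL) {
  if (is.null(stratifyBy)) {
    tab <- table(assignment$clonotype_id)
    return(data.frame(clonotype_id = names(tab),
                      n_cells = as.integer(tab), row.names = NULL))
  }
  df <- data.frame(clonotype_id = assignment$clonotype_id, stratifyBy,
                   stringsAsFactors = FALSE)
  agg <- stats::aggregate(
    list(n_cells = rep(1L, nrow(df))),
    by = df[, c("clonotype_id", names(stratifyBy)), drop = FALSE], FUN = sum)
  agg
}

## ---------------------------------------------------------------------------
## Diversity metrics
## ---------------------------------------------------------------------------

.checkAbund <- function(x) {
  if (any(x < 0) || any(x != floor(x)))
    stop("abundances must be non-negative integers")
  x <- x[x > 0]
  if (!length(x)) stop("all-zero abundance vector")
  x
}

#' Bias-corrected Chao1 richness
#'
#' `S_obs + F1*(F1 - 1) / (2*(F2 + 1))` with `F1` singletons and `F2`
#' doubletons; zero-abundance categories are ignored.
#'
#' @param abundances non-negative integer vector.
#' @return numeric richness estimate, always `>= S_obs`.
#' @export
chao1 <- function(abundances) {
  x <- .checkAbund(abundances)
  f1 <- sum(x == 1); f2 <- sum(x == 2)
  length(x) + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Normalized Shannon entropy
#'
#' `H / ln(S)` with `H = -sum p_i ln p_i` over observed categories; a single
#' category returns 0 by convention.
#'
#' @inheritParams chao1
#' @return numeric in `[0, 1]`.
#' @export
shannonNormalized <- function(abundances) {
  x <- .checkAbund(abundances)
  s <- length(x)
  if (s == 1L) return(0)
  p <- x / sum(x)
  -sum(p * log(p)) / log(s)
}

#' Heip's evenness
#'
#' `(exp(H) - 1) / (S - 1)`; a single category returns 1 by convention.
#'
#' @inheritParams chao1
#' @return numeric in `(0, 1]`.
#' @export
heipEvenness <- function(abundances) {
  x <- .checkAbund(abundances)
  s <- length(x)
  if (s == 1L) return(1)
  p <- x / sum(x)
  (exp(-sum(p * log(p))) - 1) / (s - 1)
}

## ---------------------------------------------------------------------------
## AIRR / reference table I/O
## ---------------------------------------------------------------------------

.airrCols <- c("cell_id", "locus", "junction", "junction_aa", "v_call",
               "j_call", "productive", "duplicate_count")

#' Read and write AIRR rearrangement tables
#'
#' Tab-separated AIRR-style tables with columns `cell_id`, `locus`,
#' `junction`, `junction_aa`, `v_call`, `j_call`, `productive`,
#' `duplicate_count`. `productive` is parsed from `T`/`F`/`TRUE`/`FALSE`.
#'
#' @param path file path.
#' @return `readAirr`: data.frame with the schema above.
#' @export
readAirr <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  missing <- setdiff(.airrCols, names(df))
  if (length(missing))
    stop("AIRR table missing columns: ", paste(missing, collapse = ", "))
  df$productive <- df$productive %in% c("T", "TRUE", "true")
  df$duplicate_count <- as.integer(df$duplicate_count)
  df[, .airrCols]
}

#' @rdname readAirr
#' @param records data.frame with the AIRR schema.
#' @export
writeAirr <- function(records, path) {
  missing <- setdiff(.airrCols, names(records))
  if (length(missing))
    stop("AIRR table missing columns: ", paste(missing, collapse = ", "))
  out <- records[, .airrCols]
  out$productive <- ifelse(out$productive, "T", "F")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an epitope reference table
#'
#' Tab-separated table emulating a receptor-epitope database export, with
#' columns `junction_aa`, `locus`, `epitope`, `organism`, `family`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readEpitopeReference <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("junction_aa", "locus", "epitope", "organism", "family")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("epitope reference missing columns: ",
         paste(missing, collapse = ", "))
  fam <- c("viral", "bacterial", "self", "shared", "exclusive", "unknown")
  if (!all(df$family %in% fam))
    stop("family outside vocabulary: ",
         paste(setdiff(df$family, fam), collapse = ", "))
  df[, need]
}
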