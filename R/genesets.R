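#' The 39-gene tumor-reactive signaling universe
#'
#' Gene symbols over which the tumor-reactive signaling modules are defined:
#' 21 exhaustion-relevant genes, 17 cytokine/TCR-signaling components and
#' transcription factors upstream of inhibitory-receptor genes, plus `IFNG`
#' itself.
#'
#' @return character vector of 39 unique gene symbols.
#' @export
#' @examples
#' length(tumorReactiveUniverse())
tumorReactiveUniverse <- function() {
  exhaustion <- c(
    "TIGIT", "PDCD1", "LAG3", "CTLA4", "HAVCR2", "ENTPD1", "TCF7", "TOX",
    "EOMES", "CXCL10", "CXCL9", "CXCL13", "CXCR5", "ICOS", "IL18R1",
    "IL15RA", "IL18RAP", "KLRG1", "KLRK1", "BCL6", "SLAMF6"
  )
  signaling <- c(
    "IL2", "CD28", "TNF", "SMAD3", "SMAD4", "SMAD2", "NFATC1", "NFATC3",
    "NFATC2", "MAF", "STAT2", "STAT1", "JAK3", "PRDM1", "TBX21", "YY1",
    "NFIL3"
  )
  unique(c(exhaustion, signaling, "IFNG"))
}

#' Curated CD8 subtyping and immunoregulation marker panel
#'
#' The 58-gene panel used to compare CD8+ T cell population expression across
#' processing choices (subtyping plus immunoregulation markers).
#'
#' @return character vector of 58 gene symbols.
#' @export
cd8MarkerPanel <- function() {
  c("AHR", "BATF", "BCL6", "BTLA", "CCL3", "CCL4", "CCL5", "CCR4", "CCR5",
    "CCR6", "CCR7", "CD27", "CD28", "CD4", "CD44", "PTPRC", "CD8A", "CD8B",
    "CTLA4", "CXCR3", "CXCR4", "CXCR5", "CXCR6", "ENTPD1", "EOMES", "FOXP3",
    "GATA3", "GZMA", "GZMB", "GZMK", "ICOS", "IFNG", "IKZF2", "IL10",
    "IL21R", "IL2RA", "IL2RB", "IL7R", "ITGAE", "KLF2", "KLRB1", "KLRG1",
    "LAG3", "MAF", "PDCD1", "PRF1", "REL", "SELL", "STAT1", "STAT3",
    "STAT4", "STAT6", "TBX21", "TIGIT", "TNF", "TNFRSF18", "TNFRSF9", "TOX")
}

## Canonical per-subtype module memberships. Genes marked "inferred" in the
## provenance were not placed by the primary module descriptions and are
## assigned from marker literature (see the shipped GMT description fields).
.canonicalModules <- function() {
  list(
    MSI = list(
      stem_like_progenitor = c("TCF7", "IL2", "CD28", "SLAMF6"),
      inflamed_follicular_like = c("CXCR5", "BCL6", "ICOS"),
      long_term_immunosurveillance = c("EOMES", "TBX21", "PRDM1", "KLRK1",
                                       "KLRG1"),
      tumor_reactive_exhaustion = c("IFNG", "LAG3", "PDCD1", "CTLA4",
                                    "TIGIT", "ENTPD1", "HAVCR2", "CXCL13",
                                    "NFATC2"),
      memory_differentiation = c("TOX", "IL15RA", "NFATC3", "NFIL3",
                                 "STAT1", "STAT2", "JAK3")
    ),
    MSS = list(
      long_term_immunosurveillance = c("EOMES", "PRDM1", "KLRK1", "KLRG1",
                                       "IL2", "TNF"),
      inflamed_follicular_like = c("CXCR5", "BCL6", "CD28"),
      inflamed_memory_like = c("TOX", "PDCD1", "CTLA4", "NFATC2", "NFATC3",
                               "NFATC1", "SMAD2", "SMAD3", "SMAD4", "STAT1",
                               "STAT2", "IL15RA", "IL18RAP", "IL18R1"),
      ifng_associated_dysfunctional = c("TBX21", "YY1", "NFIL3", "CXCL9",
                                        "CXCL10"),
      tolerogenic_cmaf_signaling = c("MAF", "ICOS", "LAG3", "TIGIT",
                                     "ENTPD1", "HAVCR2")
    )
  )
}

.inferredGenes <- c("SLAMF6", "JAK3", "NFATC1", "IL18R1")

#' Canonical tumor-reactive signaling modules
#'
#' The shipped 5-module configuration per CRC subtype (10 modules over the
#' 39-gene universe when both subtypes are combined). Membership provenance is
#' flagged per module: genes placed directly by the module descriptions vs a
#' small number assigned from marker literature.
#'
#' @param subtype `"MSI"`, `"MSS"` or `"both"` (all 10 modules, names prefixed
#'   with the subtype).
#' @return a [SignalingModuleSet-class].
#' @export
#' @examples
#' signalingModules("MSI")
#' length(unique(unlist(moduleGenes(signalingModules("both")))))
signalingModules <- function(subtype = c("MSI", "MSS", "both")) {
  subtype <- match.arg(subtype)
  can <- .canonicalModules()
  mods <- if (subtype == "both") {
    c(stats::setNames(can$MSI, paste0("MSI.", names(can$MSI))),
      stats::setNames(can$MSS, paste0("MSS.", names(can$MSS))))
  } else {
    can[[subtype]]
  }
  prov <- vapply(mods, function(g) {
    inf <- intersect(g, .inferredGenes)
    if (length(inf)) paste0("inferred:", paste(inf, collapse = "|"))
    else "described"
  }, character(1))
  new("SignalingModuleSet", subtype = subtype, modules = mods,
      provenance = prov)
}

#' Synthetic MAIT invariant alpha/beta CDR3 reference pairs
#'
#' A small table of invariant TRAV1-2/TRAJ33-style alpha CDR3s paired with
#' plausible beta CDR3s, shipped as a synthetic stand-in for a functionally
#' validated riboflavin-intermediate-specific MAIT TCR table. Used both by
#' [maitScore()] (as default known pairs) and by [simulateTcrRepertoire()]
#' (planted MAIT cells carry these pairs verbatim).
#'
#' @return data.frame with columns `alpha_aa`, `beta_aa`, `alpha_v`, `beta_v`.
#' @export
maitReferencePairs <- function() {
  path <- system.file("extdata", "mait_pairs_synthetic.tsv",
                      package = "iscCD8", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## GMT I/O
## ---------------------------------------------------------------------------

#' Read and write GMT gene-set files
#'
#' Standard tab-separated GMT: one set per line, `name<TAB>description<TAB>`
#' then genes.
#'
#' @param path file path.
#' @return `readGmt`: named list of character vectors, with the description
#'   column kept in attribute `"description"`.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  attr(sets, "description") <- stats::setNames(
    vapply(parts, `[`, character(1), 2L), names(sets))
  sets
}

#' @rdname readGmt
#' @param sets named list of character vectors, or a
#'   [SignalingModuleSet-class].
#' @param description optional character vector of per-set descriptions.
#' @export
writeGmt <- function(sets, path, description = NULL) {
  if (is(sets, "SignalingModuleSet")) {
    description <- sets@provenance
    sets <- moduleGenes(sets)
  }
  if (is.null(description)) description <- rep("na", length(sets))
  lines <- mapply(function(nm, desc, genes) {
    paste(c(nm, desc, genes), collapse = "\t")
  }, names(sets), description, sets)
  writeLines(lines, path)
  invisible(path)
}

#' The shipped module GMT
#'
#' Path to the versioned GMT holding all 10 canonical modules (39-gene
#' union), as written by [writeGmt()] from [signalingModules()].
#'
#' @return file path.
#' @export
moduleGmtPath <- function() {
  system.file("extdata", "signaling_modules.gmt", package = "iscCD8",
              mustWork = TRUE)
}
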