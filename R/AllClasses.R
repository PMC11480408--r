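#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom stats approx coef complete.cases cor cor.test dnorm ecdf
#'   fisher.test ks.test lm median p.adjust pnorm pt qnorm quantile rbinom
#'   rlnorm rnorm runif sd setNames t.test uniroot var wilcox.test rexp
#' @importFrom utils read.delim write.table head tail
NULL

#' Container for a DIA precursor-level experiment
#'
#' A \code{PrecursorExperiment} extends
#' \linkS4class{SummarizedExperiment}: the single \code{"intensity"} assay
#' holds per-precursor, per-sample raw intensities (\code{NA} = not
#' quantified), \code{rowData} carries the precursor metadata (protein,
#' stripped sequence, charge, modified sequence, localized site positions,
#' q-values, site-localization confidence) and \code{colData} carries the
#' sample design (kinase, WT/dead status, replicate).
#'
#' Zero intensities are coerced to \code{NA} on construction: DIA reports do
#' not emit true zeros, so a literal 0 means "not quantified".
#'
#' @seealso [PrecursorExperiment()], [readPrecursorReport()]
#' @export
setClass("PrecursorExperiment", contains = "SummarizedExperiment")

setValidity("PrecursorExperiment", function(object) {
  msg <- character()
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  rd <- rowData(object)
  need <- c("protein", "peptide", "charge", "modified", "q_value",
            "global_q_value")
  miss <- setdiff(need, colnames(rd))
  if (length(miss))
    msg <- c(msg, paste0("rowData lacks column(s): ",
                         paste(miss, collapse = ", ")))
  if (!length(msg)) {
    x <- assay(object, "intensity")
    if (any(x < 0, na.rm = TRUE)) msg <- c(msg, "negative intensities")
    if (any(x == 0, na.rm = TRUE))
      msg <- c(msg, "zero intensities must be stored as NA")
    qv <- rd$q_value
    if (any(qv < 0 | qv > 1, na.rm = TRUE)) msg <- c(msg, "q_value outside [0,1]")
  }
  if (length(msg)) msg else TRUE
})

#' Per-residue structural track of a protein model
#'
#' Holds, for one protein chain, per-residue amino acid, solvent-accessible
#' surface area (SASA, Angstrom^2), model confidence (pLDDT, 0-100), original
#' author residue numbering, heavy-atom coordinates, and optionally a
#' predicted-aligned-error (PAE) matrix. Residues are numbered 1..L
#' sequentially.
#'
#' @slot protein single protein identifier.
#' @slot residues \code{DataFrame} with columns \code{aa}, \code{sasa},
#'   \code{plddt}, \code{author_number}; one row per residue.
#' @slot atoms \code{data.frame} of heavy atoms with columns \code{residue}
#'   (1-based index), \code{element}, \code{x}, \code{y}, \code{z}. May have
#'   zero rows when only precomputed tracks are available.
#' @slot pae square numeric matrix of predicted aligned error (Angstrom), or
#'   a 0x0 matrix when absent.
#'
#' @export
setClass("StructureTrack",
  slots = c(protein = "character", residues = "DataFrame",
            atoms = "data.frame", pae = "matrix"))

setValidity("StructureTrack", function(object) {
  msg <- character()
  r <- object@residues
  need <- c("aa", "sasa", "plddt", "author_number")
  if (!all(need %in% colnames(r)))
    return("residues needs columns aa, sasa, plddt, author_number")
  if (any(r$sasa < 0, na.rm = TRUE)) msg <- c(msg, "SASA must be >= 0")
  if (any(r$plddt < 0 | r$plddt > 100, na.rm = TRUE))
    msg <- c(msg, "pLDDT must lie in [0,100]")
  if (nrow(object@atoms)) {
    if (!all(c("residue", "element", "x", "y", "z") %in%
             colnames(object@atoms)))
      msg <- c(msg, "atoms needs columns residue, element, x, y, z")
    else {
      if (any(!is.finite(as.matrix(object@atoms[, c("x", "y", "z")]))))
        msg <- c(msg, "non-finite coordinates")
      if (any(object@atoms$residue < 1 | object@atoms$residue > nrow(r)))
        msg <- c(msg, "atom residue index out of range")
    }
  }
  n <- nrow(object@pae)
  if (n && (n != ncol(object@pae) || n != nrow(r)))
    msg <- c(msg, "PAE matrix must be LxL")
  if (length(msg)) msg else TRUE
})

#' Query-anchored ortholog panel
#'
#' An alignment of orthologs anchored on a query (budding-yeast) protein,
#' together with per-species clade labels (fungi/metazoa), the map from query
#' residue positions to alignment columns, an optional phylogeny and optional
#' per-site clade equilibrium amino-acid frequencies.
#'
#' @slot query query protein identifier (must be a row of the alignment).
#' @slot alignment \code{AAStringSet} of equal-width aligned sequences,
#'   names = species/sequence ids.
#' @slot clades named character vector, one of \code{"fungi"}/\code{"metazoa"}
#'   per alignment member.
#' @slot queryColumns integer vector: alignment column of each query residue.
#' @slot tree \code{phylo} object or \code{NULL}.
#' @slot piTable \code{data.frame} of per-site equilibrium frequencies
#'   (columns \code{site}, \code{clade}, one column per amino acid,
#'   \code{adjusted_p}), or a 0-row data.frame.
#'
#' @export
setClass("OrthologPanel",
  slots = c(query = "character", alignment = "ANY", clades = "character",
            queryColumns = "integer", tree = "ANY", piTable = "data.frame"))

setValidity("OrthologPanel", function(object) {
  msg <- character()
  aln <- object@alignment
  if (!methods::is(aln, "AAStringSet")) return("alignment must be AAStringSet")
  if (length(unique(Biostrings::width(aln))) > 1)
    msg <- c(msg, "aligned sequences must share one width")
  if (!object@query %in% names(aln))
    msg <- c(msg, "query sequence absent from alignment")
  if (!all(names(aln) %in% names(object@clades)))
    msg <- c(msg, "clade labels must cover all aligned sequences")
  if (length(object@queryColumns) &&
      any(object@queryColumns < 1 |
          object@queryColumns > Biostrings::width(aln)[1]))
    msg <- c(msg, "queryColumns out of alignment range")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PrecursorExperiment", function(object) {
  cat("PrecursorExperiment:", nrow(object), "precursors x",
      ncol(object), "samples\n")
  rd <- rowData(object)
  if ("is_phospho" %in% colnames(rd))
    cat("  phosphorylated precursors:", sum(rd$is_phospho), "\n")
  cd <- colData(object)
  if (all(c("kinase", "status") %in% colnames(cd)))
    cat("  conditions:",
        paste(unique(paste(cd$kinase, cd$status, sep = ":")), collapse = " "),
        "\n")
  invisible(NULL)
})

setMethod("show", "StructureTrack", function(object) {
  cat("StructureTrack for", object@protein, "-", nrow(object@residues),
      "residues,", nrow(object@atoms), "heavy atoms",
      if (nrow(object@pae)) "(PAE present)" else "", "\n")
  invisible(NULL)
})

setMethod("show", "OrthologPanel", function(object) {
  cat("OrthologPanel anchored on", object@query, "-",
      length(object@alignment), "sequences, width",
      Biostrings::width(object@alignment)[1], "\n")
  cat("  clades:", paste(names(table(object@clades)),
                         table(object@clades), collapse = ", "), "\n")
  invisible(NULL)
})
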