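.PRECURSOR_META_COLS <- c("Protein.Ids", "Stripped.Sequence",
  "Precursor.Charge", "Modified.Sequence", "Q.Value", "Global.Q.Value",
  "PTM.Q.Value", "PTM.Site.Confidence", "Site.Positions")

#' Construct a PrecursorExperiment
#'
#' @param rowData data.frame/DataFrame of precursor metadata with columns
#'   \code{protein, peptide, charge, modified, q_value, global_q_value} and
#'   optionally \code{ptm_q_value, ptm_site_confidence, site_positions}
#'   (comma-separated 1-based protein positions of localized phosphosites).
#' @param intensity numeric matrix (precursors x samples); \code{0} is
#'   coerced to \code{NA} (not quantified).
#' @param design data.frame of sample metadata, one row per column of
#'   \code{intensity} (see [readSampleDesign()]); may be NULL.
#' @return a [PrecursorExperiment-class].
#' @export
PrecursorExperiment <- function(rowData, intensity, design = NULL) {
  rowData <- DataFrame(rowData)
  intensity <- as.matrix(intensity)
  storage.mode(intensity) <- "double"
  intensity[!is.na(intensity) & intensity == 0] <- NA_real_
  if (is.null(rownames(intensity)))
    rownames(intensity) <- precursorKey(rowData)
  if (!"site_positions" %in% colnames(rowData))
    rowData$site_positions <- ""
  rowData$site_positions[is.na(rowData$site_positions)] <- ""
  rowData$is_phospho <- nzchar(rowData$site_positions)
  cd <- if (is.null(design)) {
    DataFrame(row.names = colnames(intensity))
  } else {
    design <- as.data.frame(design)
    stopifnot(all(colnames(intensity) %in% design$sample_id))
    DataFrame(design[match(colnames(intensity), design$sample_id), ,
                     drop = FALSE],
              row.names = colnames(intensity))
  }
  se <- SummarizedExperiment(assays = list(intensity = intensity),
                             rowData = rowData, colData = cd)
  methods::new("PrecursorExperiment", se)
}

#' Unique precursor identity key
#'
#' Identity of a precursor is the triple (peptide sequence, charge, exact
#' modification set).
#'
#' @param rowData precursor metadata (needs \code{peptide}, \code{charge},
#'   \code{modified}).
#' @return character key per row.
#' @export
precursorKey <- function(rowData) {
  paste(rowData$peptide, rowData$charge, rowData$modified, sep = "/")
}

#' Read a DIA precursor intensity report
#'
#' Reads a DIA-NN-style precursor report. In the \code{"wide"} dialect each
#' sample is one intensity column (any column not among the reserved metadata
#' columns); in the \code{"long"} dialect rows carry \code{Run} and
#' \code{Intensity} columns and are cast wide. Unparseable or empty intensity
#' cells become not-quantified (\code{NA}) and their count is reported in
#' \code{metadata(x)$n_unparseable}.
#'
#' Localized phosphosite positions are taken from an optional
#' \code{Site.Positions} column (comma-separated 1-based protein positions).
#'
#' @param path TSV file path.
#' @param dialect \code{"wide"} (default) or \code{"long"}.
#' @param design optional sample design (data.frame or path for
#'   [readSampleDesign()]).
#' @param proteome optional named character vector of protein sequences used
#'   to validate site positions and acceptor letters.
#' @return a [PrecursorExperiment-class].
#' @export
readPrecursorReport <- function(path, dialect = c("wide", "long"),
                                design = NULL, proteome = NULL) {
  dialect <- match.arg(dialect)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mandatory <- c("Protein.Ids", "Stripped.Sequence", "Precursor.Charge",
                 "Modified.Sequence", "Q.Value", "Global.Q.Value")
  miss <- setdiff(mandatory, colnames(tab))
  if (length(miss))
    stop("precursor report lacks mandatory column(s): ",
         paste(miss, collapse = ", "))
  meta <- DataFrame(
    protein = tab$Protein.Ids,
    peptide = tab$Stripped.Sequence,
    charge = as.integer(tab$Precursor.Charge),
    modified = tab$Modified.Sequence,
    q_value = as.numeric(tab$Q.Value),
    global_q_value = as.numeric(tab$Global.Q.Value),
    ptm_q_value = if ("PTM.Q.Value" %in% colnames(tab))
      as.numeric(tab$PTM.Q.Value) else NA_real_,
    ptm_site_confidence = if ("PTM.Site.Confidence" %in% colnames(tab))
      as.numeric(tab$PTM.Site.Confidence) else NA_real_,
    site_positions = if ("Site.Positions" %in% colnames(tab))
      as.character(tab$Site.Positions) else "")

  n_bad <- 0L
  if (dialect == "wide") {
    sample_cols <- setdiff(colnames(tab), .PRECURSOR_META_COLS)
    if (!length(sample_cols)) stop("no sample intensity columns found")
    key <- precursorKey(meta)
    dup <- duplicated(key)
    if (any(dup))
      stop("duplicate precursor rows, first duplicate: ", key[which(dup)[1]])
    intensity <- vapply(sample_cols, function(cn) {
      raw <- tab[[cn]]
      v <- suppressWarnings(as.numeric(raw))
      n_bad <<- n_bad + sum(is.na(v) & !is.na(raw) & nzchar(trimws(raw)))
      v
    }, numeric(nrow(tab)))
    intensity <- matrix(intensity, nrow = nrow(tab),
                        dimnames = list(key, sample_cols))
  } else {
    if (!all(c("Run", "Intensity") %in% colnames(tab)))
      stop("long dialect needs columns Run and Intensity")
    key <- precursorKey(meta)
    ukey <- !duplicated(key)
    runs <- sort(unique(tab$Run))
    intensity <- matrix(NA_real_, sum(ukey), length(runs),
                        dimnames = list(key[ukey], runs))
    v <- suppressWarnings(as.numeric(tab$Intensity))
    n_bad <- sum(is.na(v) & !is.na(tab$Intensity) &
                   nzchar(trimws(tab$Intensity)))
    cell <- cbind(match(key, key[ukey]), match(tab$Run, runs))
    if (anyDuplicated(paste(cell[, 1], cell[, 2])))
      stop("duplicate (precursor, run) rows in long report")
    intensity[cell] <- v
    meta <- meta[ukey, , drop = FALSE]
  }
  if (n_bad) warning(n_bad, " unparseable intensity cells set to NA")
  if (is.character(design) && length(design) == 1)
    design <- readSampleDesign(design)
  pe <- PrecursorExperiment(meta, intensity, design)
  metadata(pe)$n_unparseable <- n_bad
  if (!is.null(proteome)) validateSites(pe, proteome)
  pe
}

#' Validate localized sites against a proteome
#'
#' Checks that each localized site position falls within its protein and that
#' the residue there is S, T or Y.
#'
#' @param x a [PrecursorExperiment-class].
#' @param proteome named character vector of protein sequences.
#' @return invisibly TRUE; errors otherwise.
#' @export
validateSites <- function(x, proteome) {
  rd <- rowData(x)
  for (i in which(rd$is_phospho)) {
    prot <- rd$protein[i]
    if (!prot %in% names(proteome)) next
    seqc <- proteome[[prot]]
    pos <- parseSitePositions(rd$site_positions[i])
    if (any(pos < 1 | pos > nchar(seqc)))
      stop("site position out of range for ", prot)
    acc <- substring(seqc, pos, pos)
    if (!all(acc %in% c("S", "T", "Y")))
      stop("non-S/T/Y acceptor at localized site of ", prot)
  }
  invisible(TRUE)
}

parseSitePositions <- function(s) {
  if (is.na(s) || !nzchar(s)) return(integer())
  as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
}

#' Write a PrecursorExperiment back to a wide TSV report
#'
#' Inverse of [readPrecursorReport()] (wide dialect); values survive a
#' write/read round trip at full precision.
#'
#' @param x a [PrecursorExperiment-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePrecursorReport <- function(x, path) {
  rd <- rowData(x)
  out <- data.frame(
    Protein.Ids = rd$protein, Stripped.Sequence = rd$peptide,
    Precursor.Charge = rd$charge, Modified.Sequence = rd$modified,
    Q.Value = rd$q_value, Global.Q.Value = rd$global_q_value,
    PTM.Q.Value = rd$ptm_q_value,
    PTM.Site.Confidence = rd$ptm_site_confidence,
    Site.Positions = rd$site_positions, check.names = FALSE)
  m <- assay(x, "intensity")
  out <- cbind(out, as.data.frame(m, check.names = FALSE))
  write.table(format(out, digits = 17, scientific = FALSE, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample design table
#'
#' TSV with columns \code{sample_id, kinase, status, replicate} and optional
#' \code{block, condition}. \code{status} must be WT, DEAD or CONTROL;
#' sample ids must be unique.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readSampleDesign <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  validateSampleDesign(d)
  d
}

#' @rdname readSampleDesign
#' @param design data.frame to validate in place.
#' @export
validateSampleDesign <- function(design) {
  need <- c("sample_id", "kinase", "status", "replicate")
  miss <- setdiff(need, colnames(design))
  if (length(miss))
    stop("design lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(design$sample_id))
    stop("duplicate sample_id in design")
  if (!all(design$status %in% c("WT", "DEAD", "CONTROL")))
    stop("status must be one of WT, DEAD, CONTROL")
  if (any(design$replicate < 1)) stop("replicate must be a positive integer")
  invisible(TRUE)
}
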