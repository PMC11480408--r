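#' Build a StructureTrack from components
#'
#' @param protein protein id.
#' @param aa character vector of one-letter residue codes (length L).
#' @param sasa,plddt optional per-residue numeric vectors (length L).
#' @param atoms optional heavy-atom data.frame with columns
#'   \code{residue, element, x, y, z}.
#' @param author_number optional original residue numbering.
#' @param pae optional LxL predicted-aligned-error matrix.
#' @return a [StructureTrack-class].
#' @export
StructureTrack <- function(protein, aa, sasa = NA_real_, plddt = NA_real_,
                           atoms = NULL, author_number = seq_along(aa),
                           pae = NULL) {
  L <- length(aa)
  res <- DataFrame(aa = aa,
                   sasa = rep_len(as.numeric(sasa), L),
                   plddt = rep_len(as.numeric(plddt), L),
                   author_number = as.integer(author_number))
  if (is.null(atoms))
    atoms <- data.frame(residue = integer(), element = character(),
                        x = numeric(), y = numeric(), z = numeric())
  if (is.null(pae)) pae <- matrix(numeric(), 0, 0)
  methods::new("StructureTrack", protein = protein, residues = res,
               atoms = atoms, pae = pae)
}

#' Read a structure model into per-chain StructureTracks
#'
#' Parses a PDB or mmCIF file (dispatch on extension, override with
#' \code{format}). One track is returned per chain; residues are renumbered
#' 1..L sequentially with the author numbering retained; alternate locations
#' resolve to the highest-occupancy copy; the per-residue mean B-factor is
#' stored as pLDDT (the convention of predicted models). Hydrogens, waters
#' and non-standard residues are dropped; a chain with no standard residues
#' is an error.
#'
#' @param path PDB/mmCIF path.
#' @param format \code{"auto"}, \code{"pdb"} or \code{"cif"}.
#' @return named list of [StructureTrack-class], one per chain.
#' @export
readStructure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  mdl <- if (format == "cif") bio3d::read.cif(path) else bio3d::read.pdb(path)
  at <- mdl$atom
  at <- at[at$type == "ATOM" & !is.na(at$resid), , drop = FALSE]
  at <- at[is.na(at$elesy) | toupper(at$elesy) != "H", , drop = FALSE]
  at <- at[!grepl("^H", at$elety), , drop = FALSE]
  one <- suppressWarnings(bio3d::aa321(at$resid))
  at <- at[!is.na(one) & one != "X", , drop = FALSE]
  if (!nrow(at)) stop("no standard-residue atoms parsed from ", path)
  # resolve altlocs to highest occupancy
  if (!all(is.na(at$alt)) && length(unique(stats::na.omit(at$alt))) > 1) {
    keyed <- paste(at$chain, at$resno, at$elety)
    occ <- if (!is.null(at$o)) at$o else 1
    ord <- order(keyed, -occ)
    at <- at[ord, , drop = FALSE][!duplicated(keyed[ord]), , drop = FALSE]
  }
  tracks <- list()
  for (ch in unique(at$chain)) {
    a <- at[at$chain == ch, , drop = FALSE]
    resno <- unique(a$resno)
    if (!length(resno)) stop("chain ", ch, " has no standard residues")
    idx <- match(a$resno, resno)
    aa1 <- bio3d::aa321(a$resid[match(resno, a$resno)])
    plddt <- vapply(seq_along(resno),
                    function(i) mean(a$b[idx == i], na.rm = TRUE), 0)
    if (all(is.na(a$b))) plddt <- rep(NA_real_, length(resno))
    elem <- if (!is.null(a$elesy) && !all(is.na(a$elesy))) toupper(a$elesy)
            else substr(gsub("[0-9]", "", a$elety), 1, 1)
    if (any(!is.finite(a$x) | !is.finite(a$y) | !is.finite(a$z)))
      stop("coordinate parse failure in ", path, " chain ", ch)
    atoms <- data.frame(residue = idx, element = elem,
                        x = a$x, y = a$y, z = a$z)
    tracks[[as.character(ch)]] <- StructureTrack(
      protein = paste0(tools::file_path_sans_ext(basename(path)), "_", ch),
      aa = aa1, plddt = plddt, atoms = atoms, author_number = resno)
  }
  tracks
}

#' Read/write precomputed per-residue SASA/pLDDT tracks
#'
#' TSV with columns \code{protein, residue, aa, sasa, plddt}.
#'
#' @param path TSV path.
#' @return named list of [StructureTrack-class] (without coordinates).
#' @export
readSasaTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein", "residue", "aa", "sasa", "plddt")
  if (!all(need %in% colnames(tab)))
    stop("sasa table needs columns ", paste(need, collapse = ", "))
  lapply(split(tab, tab$protein), function(d) {
    d <- d[order(d$residue), , drop = FALSE]
    StructureTrack(d$protein[1], aa = d$aa, sasa = d$sasa, plddt = d$plddt,
                   author_number = d$residue)
  })
}

#' @rdname readSasaTable
#' @param tracks named list of StructureTracks.
#' @export
writeSasaTable <- function(tracks, path) {
  rows <- do.call(rbind, lapply(tracks, function(t)
    data.frame(protein = t@protein, residue = seq_len(nrow(t@residues)),
               aa = t@residues$aa, sasa = t@residues$sasa,
               plddt = t@residues$plddt)))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
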