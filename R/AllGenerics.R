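#' Accessors for spurphos containers
#'
#' \code{sasa}, \code{plddt} and \code{residueLetters} return per-residue
#' vectors from a [StructureTrack-class]; \code{atomCoords} returns the
#' heavy-atom table; \code{paeMatrix} the predicted-aligned-error matrix (or
#' NULL). \code{cladeLabels}, \code{queryColumns} and \code{panelTree}
#' access an [OrthologPanel-class].
#'
#' @param x a \code{StructureTrack} or \code{OrthologPanel}.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sasa", function(x) standardGeneric("sasa"))
#' @rdname accessors
#' @export
setGeneric("plddt", function(x) standardGeneric("plddt"))
#' @rdname accessors
#' @export
setGeneric("residueLetters", function(x) standardGeneric("residueLetters"))
#' @rdname accessors
#' @export
setGeneric("atomCoords", function(x) standardGeneric("atomCoords"))
#' @rdname accessors
#' @export
setGeneric("paeMatrix", function(x) standardGeneric("paeMatrix"))
#' @rdname accessors
#' @export
setGeneric("cladeLabels", function(x) standardGeneric("cladeLabels"))
#' @rdname accessors
#' @export
setGeneric("queryColumns", function(x) standardGeneric("queryColumns"))
#' @rdname accessors
#' @export
setGeneric("panelTree", function(x) standardGeneric("panelTree"))

#' @rdname accessors
#' @export
setMethod("sasa", "StructureTrack", function(x) x@residues$sasa)
#' @rdname accessors
#' @export
setMethod("plddt", "StructureTrack", function(x) x@residues$plddt)
#' @rdname accessors
#' @export
setMethod("residueLetters", "StructureTrack", function(x) x@residues$aa)
#' @rdname accessors
#' @export
setMethod("atomCoords", "StructureTrack", function(x) x@atoms)
#' @rdname accessors
#' @export
setMethod("paeMatrix", "StructureTrack",
          function(x) if (nrow(x@pae)) x@pae else NULL)
#' @rdname accessors
#' @export
setMethod("cladeLabels", "OrthologPanel", function(x) x@clades)
#' @rdname accessors
#' @export
setMethod("queryColumns", "OrthologPanel", function(x) x@queryColumns)
#' @rdname accessors
#' @export
setMethod("panelTree", "OrthologPanel", function(x) x@tree)
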