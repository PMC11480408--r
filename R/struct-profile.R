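#' Relative solvent accessibility of a residue vector
#'
#' RSA = SASA / maxSASA(residue), clamped to [0,1].
#'
#' @param sasaVec per-residue SASA (Angstrom^2).
#' @param aa per-residue one-letter codes.
#' @param maxSasa named reference vector (see [maxSasaReference()]).
#' @return numeric RSA vector.
#' @export
relativeAccessibility <- function(sasaVec, aa,
                                  maxSasa = maxSasaReference("empirical")) {
  pmin(pmax(sasaVec / maxSasa[aa], 0), 1)
}

#' Classify a phosphosite's burial, disorder and destabilisation
#'
#' Pure threshold function: RSA < 0.2 is buried, RSA > 0.4 is exposed,
#' otherwise intermediate; the mean RSA over a +/-12-residue window
#' (truncated at chain termini, no padding) is the disorder proxy, with
#' windowed RSA >= 0.581 called disordered; a folding ddG > 2 kcal/mol is
#' called destabilising.
#'
#' @param rsaVec per-residue RSA of the whole chain.
#' @param position 1-based site position.
#' @param ddgFold optional folding ddG (kcal/mol) at the site.
#' @param window half-window for the smoothed RSA (default 12).
#' @param disorderCutoff smoothed-RSA disorder threshold (default 0.581).
#' @param buriedBelow,exposedAbove burial thresholds (defaults 0.2, 0.4).
#' @param ddgCutoff destabilisation threshold (default 2 kcal/mol).
#' @return list: rsa, windowed_rsa, disorder, burial
#'   ("buried"/"intermediate"/"exposed"), destabilising_fold (NA when no ddG).
#' @export
classifySite <- function(rsaVec, position, ddgFold = NA_real_, window = 12,
                         disorderCutoff = 0.581, buriedBelow = 0.2,
                         exposedAbove = 0.4, ddgCutoff = 2) {
  stopifnot(position >= 1, position <= length(rsaVec))
  lo <- max(1, position - window); hi <- min(length(rsaVec), position + window)
  wrsa <- mean(rsaVec[lo:hi], na.rm = TRUE)
  rsa <- rsaVec[position]
  list(rsa = rsa,
       windowed_rsa = wrsa,
       disorder = wrsa >= disorderCutoff,
       burial = if (rsa < buriedBelow) "buried"
                else if (rsa > exposedAbove) "exposed" else "intermediate",
       destabilising_fold = if (is.na(ddgFold)) NA else ddgFold > ddgCutoff)
}

#' Call protein-protein interface residues
#'
#' A residue is an interface residue iff its monomer RSA exceeds
#' \code{rsaCutoff} (0.15), its SASA drops by more than \code{dsasaCutoff}
#' (1.0 Angstrom^2) upon complex formation, and - when a cross-chain PAE
#' matrix is supplied - its minimum PAE to the partner chain is below
#' \code{paeCutoff} (8 Angstrom).
#'
#' @param sasaMonomer,sasaComplex per-residue SASA of the same chain alone
#'   and in the complex (equal lengths).
#' @param rsaMonomer per-residue monomer RSA.
#' @param crossPae optional matrix (residues x partner residues) of predicted
#'   aligned error.
#' @param rsaCutoff,dsasaCutoff,paeCutoff thresholds.
#' @return integer vector of interface residue positions.
#' @export
callInterfaceResidues <- function(sasaMonomer, sasaComplex, rsaMonomer,
                                  crossPae = NULL, rsaCutoff = 0.15,
                                  dsasaCutoff = 1.0, paeCutoff = 8) {
  if (length(sasaMonomer) != length(sasaComplex))
    stop("monomer and complex tracks differ in length")
  ok <- rsaMonomer > rsaCutoff & (sasaMonomer - sasaComplex) > dsasaCutoff
  if (!is.null(crossPae)) {
    if (nrow(crossPae) != length(sasaMonomer))
      stop("PAE matrix rows must match chain length")
    ok <- ok & apply(crossPae, 1, min) < paeCutoff
  }
  which(ok)
}

#' 1D and 3D proximity between native and spurious phosphosites
#'
#' Residue pairs on the same protein are 1D proximal iff their positions
#' differ by at most \code{d1} (4) residues, and 3D proximal iff the minimum
#' heavy-atom inter-residue distance is at most \code{d3} (8 Angstrom).
#' Sites on low-confidence residues (pLDDT < \code{plddtMin}, 70) are
#' excluded before testing. Without coordinates only 1D proximity is
#' computed.
#'
#' @param nativePos,spuriousPos integer site positions on the protein.
#' @param track [StructureTrack-class] of the protein (pLDDT required;
#'   coordinates optional).
#' @param d1,d3,plddtMin thresholds.
#' @return data.frame: native, spurious, dist1d, dist3d (NA without
#'   coordinates), proximal_1d, proximal_3d.
#' @export
proximity <- function(nativePos, spuriousPos, track, d1 = 4, d3 = 8,
                      plddtMin = 70) {
  pl <- plddt(track)
  okN <- nativePos[is.na(pl[nativePos]) | pl[nativePos] >= plddtMin]
  okS <- spuriousPos[is.na(pl[spuriousPos]) | pl[spuriousPos] >= plddtMin]
  if (!length(okN) || !length(okS))
    return(data.frame(native = integer(), spurious = integer(),
                      dist1d = integer(), dist3d = numeric(),
                      proximal_1d = logical(), proximal_3d = logical()))
  atoms <- track@atoms
  hasCoords <- nrow(atoms) > 0
  grid <- expand.grid(native = okN, spurious = okS)
  grid$dist1d <- abs(grid$native - grid$spurious)
  grid$dist3d <- NA_real_
  if (hasCoords) {
    co <- as.matrix(atoms[, c("x", "y", "z")])
    byRes <- split(seq_len(nrow(atoms)), atoms$residue)
    grid$dist3d <- vapply(seq_len(nrow(grid)), function(i) {
      ia <- byRes[[as.character(grid$native[i])]]
      ib <- byRes[[as.character(grid$spurious[i])]]
      if (is.null(ia) || is.null(ib)) return(NA_real_)
      min(sqrt(outer(rowSums(co[ia, , drop = FALSE]^2),
                     rowSums(co[ib, , drop = FALSE]^2), `+`) -
                 2 * co[ia, , drop = FALSE] %*% t(co[ib, , drop = FALSE])))
    }, 0)
  }
  grid$proximal_1d <- grid$dist1d <= d1
  grid$proximal_3d <- if (hasCoords) grid$dist3d <= d3 else NA
  grid
}

#' Scan phosphosites for short linear motif (SLiM) matches
#'
#' A site matches a motif iff the regular expression matches the protein
#' sequence with the phosphoacceptor inside the match span (or exactly at
#' \code{acceptor_offset} from the match start when the motif declares one),
#' the site's burial class is exposed, and the position lies outside all
#' annotated domain spans.
#'
#' @param sequence protein sequence.
#' @param sites data.frame with \code{position} and \code{burial}.
#' @param motifs data.frame with \code{motif_id, regex} and optional
#'   \code{acceptor_offset} (0-based within the match).
#' @param domains optional data.frame with \code{start, end} spans for this
#'   protein.
#' @return data.frame: position, motif_id (one row per match).
#' @export
slimScan <- function(sequence, sites, motifs, domains = NULL) {
  inDomain <- function(pos) {
    if (is.null(domains) || !nrow(domains)) return(FALSE)
    any(pos >= domains$start & pos <= domains$end)
  }
  out <- list()
  for (k in seq_len(nrow(motifs))) {
    mm <- tryCatch(
      suppressWarnings(gregexpr(motifs$regex[k], sequence, perl = TRUE)[[1]]),
      error = function(e)
        stop("invalid regex for motif ", motifs$motif_id[k]))
    if (mm[1] == -1) next
    starts <- as.integer(mm); lens <- attr(mm, "match.length")
    off <- motifs$acceptor_offset[k]
    for (i in seq_len(nrow(sites))) {
      pos <- sites$position[i]
      if (sites$burial[i] != "exposed" || inDomain(pos)) next
      hit <- if (!is.na(off))
        any(starts + off == pos)
      else any(pos >= starts & pos <= starts + lens - 1)
      if (hit)
        out[[length(out) + 1]] <- data.frame(position = pos,
                                             motif_id = motifs$motif_id[k])
    }
  }
  if (!length(out))
    return(data.frame(position = integer(), motif_id = character()))
  unique(do.call(rbind, out))
}

#' Test phosphosite bias toward protein termini
#'
#' One-sample two-sided Kolmogorov-Smirnov test of the relative site
#' positions (position / protein length) against Uniform(0,1); the folded
#' distance to the nearest terminus, min(r, 1-r), is reported as a secondary
#' statistic.
#'
#' @param positions site positions.
#' @param lengths protein length per site.
#' @return list: relative, folded, ks_stat, p (with a warning below 10
#'   sites).
#' @export
terminiBias <- function(positions, lengths) {
  r <- positions / lengths
  stopifnot(all(r > 0 & r <= 1))
  if (length(r) < 10) warning("fewer than 10 sites; KS p is unreliable")
  ks <- suppressWarnings(ks.test(r, "punif"))
  list(relative = r, folded = pmin(r, 1 - r),
       ks_stat = unname(ks$statistic), p = ks$p.value)
}

#' Summarise structural site profiles per kinase group
#'
#' @param profiles data.frame with one row per site: \code{group} (e.g. pY,
#'   pYd, v-SRC, pST), \code{burial}, \code{disorder},
#'   \code{destabilising_fold}, and optional logical columns
#'   \code{interface_destabilising}, \code{slim}, \code{proximal_1d},
#'   \code{proximal_3d}.
#' @return data.frame of per-group fractions; a column whose inputs are all
#'   NA (e.g. no ddG table loaded) is reported as NA, not 0.
#' @export
profileSummary <- function(profiles) {
  frac <- function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  do.call(rbind, lapply(split(profiles, profiles$group), function(d) {
    data.frame(
      group = d$group[1], n = nrow(d),
      buried = frac(d$burial == "buried"),
      exposed = frac(d$burial == "exposed"),
      disordered = frac(d$disorder),
      destabilising_fold = frac(d$destabilising_fold),
      interface_destabilising = if ("interface_destabilising" %in% names(d))
        frac(d$interface_destabilising) else NA_real_,
      slim = if ("slim" %in% names(d)) frac(d$slim) else NA_real_,
      proximal_1d = if ("proximal_1d" %in% names(d)) frac(d$proximal_1d)
        else NA_real_,
      proximal_3d = if ("proximal_3d" %in% names(d)) frac(d$proximal_3d)
        else NA_real_)
  }))
}
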