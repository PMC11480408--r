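#' Simulate FoldX-style energy-term tables and variant-effect score matrices
#'
#' The energy table is built from a per-site latent severity: the pY column
#' follows it closely and every amino-acid column tracks it with a chosen
#' similarity (so the derived pY weights have a known ranking). The score
#' matrix plants a set of "deleterious" positions whose scores are uniformly
#' more harmful (lower, in the lower-is-harmful orientation) across all
#' substitutions.
#'
#' @param nSites sites in the energy table.
#' @param similarity named numeric in [0,1] per non-Y amino acid: correlation
#'   target of that column to the pY column (defaults: acidic D/E high, the
#'   rest moderate-to-low).
#' @param proteins character vector of protein ids for the score matrix.
#' @param positionsPerProtein scored positions per protein.
#' @param deleteriousFraction fraction of positions planted as deleterious
#'   (a fixed count of round(fraction x positions) per protein).
#' @param effectSize score separation of planted positions (in noise sds).
#' @param seed integer seed.
#' @return list: \code{energy} (site, substitution, term, ddg),
#'   \code{scores} (protein, position, 19 amino-acid columns),
#'   \code{truth} (planted deleterious positions; similarity vector).
#' @export
genVepTables <- function(nSites = 100, similarity = NULL,
                         proteins = sprintf("prot%03d", 1:5),
                         positionsPerProtein = 40,
                         deleteriousFraction = 0.1, effectSize = 4,
                         seed = 1) {
  aaSub <- setdiff(AA20, "Y")
  if (is.null(similarity)) {
    similarity <- setNames(rep(0.3, 19), aaSub)
    similarity[c("D", "E")] <- c(0.85, 0.8)   # phosphomimetics track pY
    similarity[c("S", "T")] <- 0.5
    similarity[c("W", "F", "L", "I", "V")] <- 0.1
  }
  terms <- c("backbone_hbond", "vdw", "electrostatics", "polar_solvation",
             "hydrophobic_solvation", "vdw_clashes", "sidechain_entropy",
             "mainchain_entropy", "torsional_clash", "backbone_clash",
             "helix_dipole", "ionisation")
  withSeed(seed, {
    z <- rnorm(nSites)
    energy <- list()
    for (t in terms) {
      py <- z + rnorm(nSites, 0, 0.2)
      energy[[length(energy) + 1]] <- data.frame(
        site = seq_len(nSites), substitution = "pY", term = t, ddg = py)
      for (aa in aaSub) {
        s <- similarity[[aa]]
        v <- s * z + sqrt(max(0, 1 - s^2)) * rnorm(nSites)
        energy[[length(energy) + 1]] <- data.frame(
          site = seq_len(nSites), substitution = aa, term = t, ddg = v)
      }
    }
    scores <- list(); planted <- list()
    nDel <- round(deleteriousFraction * positionsPerProtein)
    for (p in proteins) {
      pos <- seq_len(positionsPerProtein)
      del <- seq_along(pos) %in% sample(pos, nDel)
      base <- matrix(rnorm(positionsPerProtein * 19), ncol = 19,
                     dimnames = list(NULL, aaSub))
      base[del, ] <- base[del, ] - effectSize
      scores[[p]] <- data.frame(protein = p, position = pos, base,
                                check.names = FALSE)
      planted[[p]] <- data.frame(protein = p, position = pos,
                                 deleterious = del)
    }
    list(energy = do.call(rbind, energy),
         scores = do.call(rbind, scores),
         truth = list(deleterious = do.call(rbind, planted),
                      similarity = similarity, seed = seed))
  })
}
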