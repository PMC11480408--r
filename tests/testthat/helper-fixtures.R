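# small in-code fixtures shared across test files

toyReportLines <- function() {
  hdr <- paste("Protein.Ids", "Stripped.Sequence", "Precursor.Charge",
               "Modified.Sequence", "Q.Value", "Global.Q.Value",
               "PTM.Q.Value", "PTM.Site.Confidence", "Site.Positions",
               "s1", "s2", "s3", sep = "\t")
  r1 <- paste("P1", "AAASK", 2, "AAAS(UniMod:21)K", 0.001, 0.002, 0.003,
              0.95, "4", 1000, 2000, 1500, sep = "\t")
  r2 <- paste("P1", "AAASK", 2, "AAASK", 0.001, 0.002, "NA", "NA", "",
              5000, "", 4000, sep = "\t")
  c(hdr, r1, r2)
}

writeToyReport <- function(path = tempfile(fileext = ".tsv"),
                           lines = toyReportLines()) {
  writeLines(lines, path)
  path
}

toyPdbLines <- function() c(
  "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00 91.30           N",
  "ATOM      2  CA  GLY A   1       1.450   0.000   0.000  1.00 91.30           C",
  "ATOM      3  C   GLY A   1       2.000   1.400   0.000  1.00 91.30           C",
  "ATOM      4  CA  ALA A   2       4.000   2.000   0.500  1.00 77.20           C",
  "ATOM      5  CB  ALA A   2       4.500   3.300   1.200  1.00 77.20           C",
  "ATOM      6  CA  TYR A   3       7.500   2.500   1.000  1.00 55.10           C",
  "END")

toyCifLines <- function() c(
  "data_toy", "loop_",
  "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
  "_atom_site.label_atom_id", "_atom_site.label_alt_id",
  "_atom_site.label_comp_id", "_atom_site.label_asym_id",
  "_atom_site.label_entity_id", "_atom_site.label_seq_id",
  "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
  "_atom_site.Cartn_z", "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
  "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
  "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
  "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num",
  "ATOM 1 N N . GLY A 1 1 ? 0.000 0.000 0.000 1.00 91.30 ? 1 GLY A N 1",
  "ATOM 2 C CA . GLY A 1 1 ? 1.450 0.000 0.000 1.00 91.30 ? 1 GLY A CA 1",
  "ATOM 3 C C . GLY A 1 1 ? 2.000 1.400 0.000 1.00 91.30 ? 1 GLY A C 1",
  "ATOM 4 C CA . ALA A 1 2 ? 4.000 2.000 0.500 1.00 77.20 ? 2 ALA A CA 1",
  "ATOM 5 C CB . ALA A 1 2 ? 4.500 3.300 1.200 1.00 77.20 ? 2 ALA A CB 1",
  "ATOM 6 C CA . TYR A 1 3 ? 7.500 2.500 1.000 1.00 55.10 ? 3 TYR A CA 1")

# random rigid (proper) rotation matrix
randomRotation <- function() {
  qr.Q(qr(matrix(rnorm(9), 3))) * sample(c(-1, 1), 1) -> Q
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# exhaustive two-sided Fisher p for a 2x2 table, by hypergeometric
# enumeration over all tables with the observed margins
fisherOracle <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- dhyper(ks, r1, n - r1, c1)
  pObs <- dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# GLS correlation under Brownian covariance (oracle for PIC through-origin
# correlation on small trees)
glsCorOracle <- function(tree, x, y) {
  C <- ape::vcv(tree)
  x <- x[rownames(C)]; y <- y[rownames(C)]
  Ci <- solve(C)
  one <- rep(1, length(x))
  mx <- sum(Ci %*% x) / sum(Ci)
  my <- sum(Ci %*% y) / sum(Ci)
  xc <- x - mx; yc <- y - my
  (t(xc) %*% Ci %*% yc) /
    sqrt((t(xc) %*% Ci %*% xc) * (t(yc) %*% Ci %*% yc))
}
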