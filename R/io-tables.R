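#' Read a FoldX-style per-run ddG table
#'
#' TSV with columns \code{protein, position, run, ddg} and an optional
#' \code{substitution} column (for energy/interface tables a \code{partner}
#' column is also accepted). The per-site ddG is the mean over runs; rows
#' whose position cannot be parsed as a positive integer are skipped with a
#' warning.
#'
#' @param path TSV path.
#' @return data.frame with one row per (protein, position[, partner]):
#'   \code{ddg} (mean over runs), \code{n_runs}, \code{partial} flag when
#'   fewer runs than the maximum observed were present.
#' @export
readDdgTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein", "position", "run", "ddg")
  if (!all(need %in% colnames(tab)))
    stop("ddG table needs columns ", paste(need, collapse = ", "))
  pos <- suppressWarnings(as.integer(tab$position))
  bad <- is.na(pos) | pos < 1
  if (any(bad)) {
    warning(sum(bad), " ddG rows with unmappable site ids skipped")
    tab <- tab[!bad, , drop = FALSE]; pos <- pos[!bad]
  }
  if (any(is.na(suppressWarnings(as.numeric(tab$ddg))))) {
    i <- which(is.na(suppressWarnings(as.numeric(tab$ddg))))[1]
    stop("malformed ddG value at data row ", i)
  }
  tab$position <- pos
  keycols <- intersect(c("protein", "position", "partner"), colnames(tab))
  key <- do.call(paste, c(tab[keycols], sep = "\r"))
  agg <- lapply(split(seq_len(nrow(tab)), key), function(i) {
    out <- tab[i[1], keycols, drop = FALSE]
    out$ddg <- mean(as.numeric(tab$ddg[i]))
    out$n_runs <- length(i)
    out
  })
  res <- do.call(rbind, agg)
  res$partial <- res$n_runs < max(res$n_runs)
  rownames(res) <- NULL
  res
}

#' Read a per-substitution variant-effect score matrix
#'
#' TSV with columns \code{protein, position} plus one column per substitution
#' amino acid (the 19 non-wildtype letters; a wildtype column, if present, is
#' ignored downstream).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readScoreMatrix <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("protein", "position") %in% colnames(tab)))
    stop("score matrix needs columns protein, position")
  tab
}

#' Read per-site clade equilibrium-frequency tables
#'
#' TSV with columns \code{protein, site, clade}, one column per amino acid,
#' and \code{adjusted_p}.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readPiFrequencies <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein", "site", "clade", "adjusted_p")
  if (!all(need %in% colnames(tab)))
    stop("pi table needs columns ", paste(need, collapse = ", "))
  tab
}

#' Read colony growth curves
#'
#' CSV with columns \code{strain, condition, replicate, time_h, size,
#' circularity}. Within each colony, times must be strictly increasing and at
#' least three time points present.
#'
#' @param path CSV path.
#' @return data.frame ordered by colony then time.
#' @export
readGrowthCurves <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("strain", "condition", "replicate", "time_h", "size",
            "circularity")
  miss <- setdiff(need, colnames(d))
  if (length(miss))
    stop("growth table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(d$size < 0)) stop("colony sizes must be >= 0")
  d <- d[order(d$strain, d$condition, d$replicate, d$time_h), , drop = FALSE]
  ok <- vapply(split(d$time_h,
                     paste(d$strain, d$condition, d$replicate, sep = "\r")),
               function(t) length(t) >= 3 && all(diff(t) > 0), TRUE)
  if (!all(ok)) stop("each colony needs >= 3 strictly increasing time points")
  d
}

#' Read a proteome FASTA as plain sequences
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
readProteomeFasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
}

#' Read clade labels
#'
#' TSV with columns \code{species, clade}.
#' @param path TSV path.
#' @return named character vector species -> clade.
#' @export
readCladeLabels <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("species", "clade") %in% colnames(d)))
    stop("clade table needs columns species, clade")
  setNames(d$clade, d$species)
}

#' Read a SLiM motif table
#'
#' TSV with columns \code{motif_id, regex, acceptor_offset} where
#' \code{acceptor_offset} is the 0-based offset of the phosphoacceptor within
#' a regex match.
#' @param path TSV path.
#' @return data.frame.
#' @export
readMotifTable <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("motif_id", "regex") %in% colnames(d)))
    stop("motif table needs columns motif_id, regex")
  if (!"acceptor_offset" %in% colnames(d)) d$acceptor_offset <- NA_integer_
  d
}

#' Read domain annotations
#'
#' TSV with columns \code{protein, domain, start, end} (1-based inclusive).
#' @param path TSV path.
#' @return data.frame.
#' @export
readDomainTable <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("protein", "domain", "start", "end") %in% colnames(d)))
    stop("domain table needs columns protein, domain, start, end")
  if (any(d$start < 1 | d$end < d$start)) stop("invalid domain spans")
  d
}

#' Read a YAML run configuration
#'
#' @param path YAML path.
#' @return named list.
#' @export
readConfig <- function(path) yaml::read_yaml(path)

#' Write a generic TSV at full precision
#'
#' @param x data.frame.
#' @param path output path.
#' @return path, invisibly.
#' @export
writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
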