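#' Pairwise uncorrected p-distances with pairwise deletion
#'
#' For every pair of aligned sequences, the distance is the number of
#' mismatching sites divided by the number of compared sites, where a site
#' is compared only when both characters are unambiguous bases (A, C, G,
#' T; case-insensitive).  Gaps (\code{-}) and ambiguity codes are excluded
#' per pair (pairwise deletion), so denominators differ between pairs.
#' Pairs with zero comparable sites are flagged \code{NA} with a warning.
#'
#' @param aln A [Biostrings::DNAStringSet-class] of equal-length aligned
#'   sequences with unique names, or a named character vector.
#' @param minSites Pairs compared over fewer sites than this trigger a
#'   warning (short-fragment artifacts deflate distances; default 200).
#' @return A [DistanceMatrix-class].
#' @examples
#' aln <- Biostrings::DNAStringSet(c(s1 = "ACGT", s2 = "ACGA", s3 = "AC-T"))
#' distances(pairwisePDistance(aln, minSites = 0))
#' @export
pairwisePDistance <- function(aln, minSites = 200) {
  if (is.character(aln)) aln <- Biostrings::DNAStringSet(aln)
  n <- length(aln)
  if (n < 2L) stop("need at least two sequences")
  ids <- names(aln)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
    stop("sequences must carry unique non-empty ids")
  if (length(unique(Biostrings::width(aln))) != 1L)
    stop("sequences must be aligned to equal length")
  m <- toupper(as.matrix(aln))
  valid <- m == "A" | m == "C" | m == "G" | m == "T"
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  sites <- matrix(0L, n, n, dimnames = list(ids, ids))
  diag(sites) <- as.integer(rowSums(valid))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      comp <- valid[i, ] & valid[j, ]
      nc <- sum(comp)
      sites[i, j] <- sites[j, i] <- nc
      d[i, j] <- d[j, i] <-
        if (nc == 0L) NA_real_ else sum(m[i, comp] != m[j, comp]) / nc
    }
  }
  offSites <- sites[upper.tri(sites)]
  if (any(offSites == 0L))
    warning("some sequence pairs share no comparable sites; flagged NA")
  if (any(offSites > 0L & offSites < minSites))
    warning("some pairs compared over fewer than ", minSites,
            " sites; their distances may be unreliable")
  new("DistanceMatrix", d = d, sites = sites)
}

#' Summarize distances within and between clades
#'
#' Aggregates the pairwise distances of a [DistanceMatrix-class] by clade:
#' one row per unordered clade pair (all cross-clade sequence pairs) and
#' one per clade with itself (all distinct within-clade pairs; singleton
#' clades get no intra row).  This is the structure of published
#' clade-by-clade 16S distance tables: mean, SD, range, and the number of
#' sequence pairs behind each cell.
#'
#' @param dm A [DistanceMatrix-class].
#' @param clades Named character vector mapping every sequence id in
#'   \code{dm} to a clade label.
#' @return data.frame with columns \code{cladeA}, \code{cladeB},
#'   \code{mean}, \code{sd}, \code{min}, \code{max},
#'   \code{nComparisons}.  \code{cladeA == cladeB} marks intra-clade rows.
#'   SD is \code{NA} for a single comparison.
#' @export
cladePairSummary <- function(dm, clades) {
  stopifnot(is(dm, "DistanceMatrix"))
  ids <- rownames(distances(dm))
  missing <- setdiff(ids, names(clades))
  if (length(missing))
    stop("no clade assignment for sequence(s): ",
         paste(missing, collapse = ", "))
  cl <- clades[ids]
  labs <- sort(unique(cl))
  d <- distances(dm)
  out <- list()
  for (a in seq_along(labs)) {
    for (b in a:length(labs)) {
      ia <- which(cl == labs[a])
      ib <- which(cl == labs[b])
      if (a == b) {
        if (length(ia) < 2L) next
        pairs <- utils::combn(ia, 2L)
        vals <- d[cbind(pairs[1, ], pairs[2, ])]
      } else {
        vals <- as.vector(d[ia, ib, drop = FALSE])
      }
      vals <- vals[!is.na(vals)]
      if (!length(vals)) next
      out[[length(out) + 1L]] <- data.frame(
        cladeA = labs[a], cladeB = labs[b],
        mean = mean(vals),
        sd = if (length(vals) > 1L) stats::sd(vals) else NA_real_,
        min = min(vals), max = max(vals),
        nComparisons = length(vals), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Classify a p-distance into divergence categories
#'
#' Bins used for 16S divergence between amphibian lineages: low below 3%,
#' moderate 3--5%, high above 5%, very high above 7%.  Boundaries are
#' resolved as \code{[0, 0.03)} low, \code{[0.03, 0.05]} moderate,
#' \code{(0.05, 0.07]} high, \code{(0.07, 1]} very high.
#'
#' @param p p-distance(s) in \code{[0, 1]} (vectorized).
#' @return Factor with levels \code{low}, \code{moderate}, \code{high},
#'   \code{very_high}.
#' @examples
#' classifyDivergence(c(0.025, 0.03, 0.057, 0.12))
#' @export
classifyDivergence <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p must lie in [0, 1]")
  res <- character(length(p))
  res[p < 0.03] <- "low"
  res[p >= 0.03 & p <= 0.05] <- "moderate"
  res[p > 0.05 & p <= 0.07] <- "high"
  res[p > 0.07] <- "very_high"
  factor(res, levels = c("low", "moderate", "high", "very_high"))
}

#' Read a clade-map file
#'
#' Two-column delimited text (id, clade), with or without a header.
#'
#' @param path Path to the file.
#' @param sep Field separator (default auto: comma or tab).
#' @return Named character vector mapping sequence id to clade label.
#' @export
readCladeMap <- function(path, sep = NULL) {
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- utils::read.table(path, sep = sep, header = FALSE,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  if (tolower(df[1, 1]) %in% c("id", "sequence", "seqid")) df <- df[-1, ]
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Write a clade-pair summary as a square matrix table
#'
#' Mirrors the layout of published clade distance tables: means below the
#' diagonal, pair counts above, intra-clade means on the diagonal.
#'
#' @param summary Output of [cladePairSummary()] (or any data.frame with
#'   the same columns).
#' @param path Optional path; when given the matrix is written as CSV.
#' @return The character matrix, invisibly when written.
#' @export
summaryMatrixTable <- function(summary, path = NULL) {
  labs <- sort(unique(c(summary$cladeA, summary$cladeB)))
  m <- matrix("", length(labs), length(labs), dimnames = list(labs, labs))
  for (r in seq_len(nrow(summary))) {
    a <- match(summary$cladeA[r], labs)
    b <- match(summary$cladeB[r], labs)
    if (a == b) {
      m[a, a] <- sprintf("%.4g", summary$mean[r])
    } else {
      m[max(a, b), min(a, b)] <- sprintf("%.4g", summary$mean[r])
      m[min(a, b), max(a, b)] <- as.character(summary$nComparisons[r])
    }
  }
  if (!is.null(path)) {
    utils::write.csv(m, path)
    return(invisible(m))
  }
  m
}
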