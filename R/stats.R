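#' Correlation-matrix PCA of call variables
#'
#' Standardizes each column to zero mean and unit SD, eigendecomposes the
#' correlation matrix, and retains components with eigenvalue strictly
#' greater than 1.  Percent variance per component is
#' \code{eigenvalue / nVariables * 100} (eigenvalues of a correlation PCA
#' sum to the number of variables).  Each loading column's sign is fixed
#' so its largest-magnitude entry is positive, making loadings tables
#' reproducible across runs.
#'
#' @param x Numeric matrix or data.frame; rows are individuals (typically
#'   per-male averages over their calls), columns the call variables.
#' @return A [PCAResult-class].
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(100), 20, 5)
#' correlationPca(x)
#' @export
correlationPca <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("feature matrix must be numeric")
  if (nrow(x) < 3L) stop("need at least 3 rows")
  if (anyNA(x)) stop("feature matrix must have no missing cells")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(x)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("zero-variance column(s): ", paste(bad, collapse = ", "))
  }
  z <- scale(x)
  ce <- eigen(stats::cor(x), symmetric = TRUE)
  ord <- order(ce$values, decreasing = TRUE)
  ev <- pmax(ce$values[ord], 0)
  load <- ce$vectors[, ord, drop = FALSE]
  for (k in seq_len(ncol(load))) {
    i <- which.max(abs(load[, k]))
    if (load[i, k] < 0) load[, k] <- -load[, k]
  }
  rownames(load) <- colnames(x)
  colnames(load) <- paste0("PC", seq_len(ncol(load)))
  retained <- sum(ev > 1)
  scores <- z %*% load[, seq_len(max(retained, 1L)), drop = FALSE]
  if (retained == 0L) scores <- scores[, 0L, drop = FALSE]
  new("PCAResult", loadings = load, eigenvalues = ev,
      percentVariance = percentVariance(ev, ncol(x)),
      retained = as.integer(retained), scores = scores)
}

#' Percent variance explained from correlation-PCA eigenvalues
#'
#' @param eigenvalues Eigenvalues of the correlation matrix.
#' @param nVariables Number of variables (defaults to the number of
#'   eigenvalues; the eigenvalues of a full decomposition sum to it).
#' @return \code{eigenvalues / nVariables * 100}.
#' @examples
#' percentVariance(2.59, nVariables = 5)  # 51.8
#' @export
percentVariance <- function(eigenvalues, nVariables = length(eigenvalues)) {
  eigenvalues / nVariables * 100
}

#' Welch two-sample t-test from summary statistics
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom, computed from group means, SDs and sample sizes -- the form
#' needed when only published summary tables are available.  The rounded
#' df is reported alongside for table display.
#'
#' @param m1,s1,n1 Mean, SD and size of group 1.
#' @param m2,s2,n2 Mean, SD and size of group 2.
#' @return List with \code{t}, \code{df}, \code{dfRounded},
#'   \code{p} (two-sided).
#' @examples
#' welchFromSummary(26.0, 0.9, 8, 23.8, 1.5, 185)  # t ~ 6.52, df rounds to 9
#' @export
welchFromSummary <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  if (s1 < 0 || s2 < 0 || (s1 == 0 && s2 == 0))
    stop("SDs must be non-negative and not both zero")
  v1 <- s1^2 / n1
  v2 <- s2^2 / n2
  tstat <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = tstat, df = df, dfRounded = round(df),
       p = 2 * stats::pt(-abs(tstat), df))
}

#' Pairwise Welch tests on retained principal-component scores
#'
#' For every pair of groups with at least two members each, a Welch
#' t-test on each retained PC.  No multiplicity correction is applied by
#' default; set \code{adjust = "holm"} for Holm-adjusted p-values.
#'
#' @param pca A [PCAResult-class] with at least one retained component.
#' @param groups Group label per score row.
#' @param adjust \code{"none"} (default) or \code{"holm"}.
#' @return data.frame with columns \code{pc}, \code{groupA},
#'   \code{groupB}, \code{t}, \code{df}, \code{p}; empty when fewer than
#'   two groups are testable (groups of size < 2 are skipped with a
#'   warning).
#' @export
pcGroupTests <- function(pca, groups, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  stopifnot(is(pca, "PCAResult"))
  groups <- as.character(groups)
  if (length(groups) != nrow(pca@scores))
    stop("one group label per score row required")
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2L]
  if (length(small))
    warning("group(s) with fewer than 2 members skipped: ",
            paste(small, collapse = ", "))
  usable <- sort(names(sizes)[sizes >= 2L])
  empty <- data.frame(pc = character(), groupA = character(),
                      groupB = character(), t = numeric(), df = numeric(),
                      p = numeric(), stringsAsFactors = FALSE)
  if (length(usable) < 2L || pca@retained < 1L) return(empty)
  out <- empty
  for (k in seq_len(pca@retained)) {
    sc <- pca@scores[, k]
    for (a in seq_len(length(usable) - 1L)) {
      for (b in seq(a + 1L, length(usable))) {
        xa <- sc[groups == usable[a]]
        xb <- sc[groups == usable[b]]
        wt <- welchFromSummary(mean(xa), stats::sd(xa), length(xa),
                               mean(xb), stats::sd(xb), length(xb))
        out <- rbind(out, data.frame(
          pc = colnames(pca@scores)[k], groupA = usable[a],
          groupB = usable[b], t = wt$t, df = wt$df, p = wt$p,
          stringsAsFactors = FALSE))
      }
    }
  }
  if (adjust == "holm") out$p <- stats::p.adjust(out$p, "holm")
  out
}

#' Per-group summary statistics
#'
#' n, mean, sample SD (n-1 denominator; NA for singletons), minimum and
#' maximum per group -- the layout of published body-size tables.
#'
#' @param values Numeric vector (e.g. SVL in mm).
#' @param groups Group label per value.
#' @return data.frame with one row per non-empty group; empty groups
#'   (levels with no values) are omitted with a warning.
#' @examples
#' summarizeGroups(c(1, 2, 3), c("C", "C", "C"))
#' @export
summarizeGroups <- function(values, groups) {
  if (length(values) != length(groups))
    stop("every value must be labeled")
  groups <- as.character(groups)
  keep <- !is.na(values)
  if (is.factor(groups)) groups <- droplevels(groups)
  empties <- setdiff(unique(groups), unique(groups[keep]))
  if (length(empties))
    warning("empty group(s) omitted: ", paste(empties, collapse = ", "))
  values <- values[keep]; groups <- groups[keep]
  sp <- split(values, groups)
  out <- data.frame(
    group = names(sp),
    n = lengths(sp),
    mean = vapply(sp, mean, numeric(1)),
    sd = vapply(sp, function(v)
      if (length(v) > 1L) stats::sd(v) else NA_real_, numeric(1)),
    min = vapply(sp, min, numeric(1)),
    max = vapply(sp, max, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
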