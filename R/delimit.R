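#' Cluster lineages by genetic distance
#'
#' Single-linkage agglomeration on inter-clade mean p-distances: two
#' clades share a candidate-species group if and only if they are
#' connected by a chain of pairwise means at or below the threshold.
#' Groups with distances above the threshold (default 3%) are treated as
#' separate candidate species.  The result is deterministic and
#' independent of row order.
#'
#' @param summary data.frame with columns \code{cladeA}, \code{cladeB},
#'   \code{mean} covering every unordered inter-clade pair (intra rows,
#'   \code{cladeA == cladeB}, are ignored), e.g. from
#'   [cladePairSummary()].
#' @param threshold Distance threshold; means \code{<= threshold} merge
#'   (default 0.03, the 3% rule).
#' @param linkage Either \code{"single"} (default) or \code{"complete"};
#'   complete linkage requires all cross-pair means within the threshold.
#' @return A \code{lineagePartition}: list with \code{groups} (list of
#'   character vectors, each sorted; groups ordered by first member) and
#'   an empty \code{overrides} log.
#' @examples
#' s <- data.frame(cladeA = c("A", "A", "B"), cladeB = c("B", "C", "C"),
#'                 mean = c(0.02, 0.08, 0.09))
#' clusterLineages(s, threshold = 0.03)$groups
#' @export
clusterLineages <- function(summary, threshold = 0.03,
                            linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  inter <- summary[summary$cladeA != summary$cladeB, , drop = FALSE]
  labs <- sort(unique(c(inter$cladeA, inter$cladeB, summary$cladeA)))
  n <- length(labs)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  means <- stats::setNames(inter$mean, key(inter$cladeA, inter$cladeB))
  if (n > 1L) {
    allPairs <- utils::combn(labs, 2L)
    missing <- !(key(allPairs[1, ], allPairs[2, ]) %in% names(means))
    if (any(missing))
      stop("missing inter-clade mean for pair(s): ",
           paste(apply(allPairs[, missing, drop = FALSE], 2L, paste,
                       collapse = "-"), collapse = ", "))
  }
  # union-find over edges at or below the threshold
  parent <- stats::setNames(seq_len(n), labs)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (nm in names(means)) {
    if (means[[nm]] <= threshold) {
      ab <- strsplit(nm, "\r", fixed = TRUE)[[1]]
      ra <- find(match(ab[1], labs)); rb <- find(match(ab[2], labs))
      if (ra != rb) parent[rb] <- ra
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- unname(lapply(split(labs, comp), sort))
  if (linkage == "complete") {
    # split any single-linkage group whose members are not pairwise close
    refined <- list()
    for (g in groups) {
      rem <- g
      while (length(rem)) {
        grp <- rem[1]; rem <- rem[-1]
        repeat {
          ok <- vapply(rem, function(x)
            all(means[key(x, grp)] <= threshold), logical(1))
          if (!any(ok)) break
          grp <- sort(c(grp, rem[ok])); rem <- rem[!ok]
        }
        refined[[length(refined) + 1L]] <- grp
      }
    }
    groups <- refined
  }
  groups <- groups[order(vapply(groups, `[`, character(1), 1L))]
  structure(list(groups = groups,
                 overrides = data.frame(lineage = character(),
                                        action = character(),
                                        rationale = character(),
                                        stringsAsFactors = FALSE)),
            class = "lineagePartition")
}

#' @export
print.lineagePartition <- function(x, ...) {
  cat(sprintf("Lineage partition: %d group(s)\n", length(x$groups)))
  for (g in x$groups) cat("  {", paste(g, collapse = ", "), "}\n")
  if (nrow(x$overrides))
    cat(sprintf("%d analyst override(s) applied\n", nrow(x$overrides)))
  invisible(x)
}

#' Apply documented analyst overrides to a partition
#'
#' Threshold clustering can be overruled by explicit, logged decisions --
#' e.g. promoting a lineage whose apparently low divergence is an artifact
#' of a short sequence fragment.  Overrides are never inferred; each one
#' names a lineage, an action, and a free-text rationale that is recorded
#' verbatim in the result.
#'
#' @param partition A \code{lineagePartition} from [clusterLineages()].
#' @param overrides data.frame with columns \code{lineage},
#'   \code{action} (\code{"split_out"} or \code{"merge_into:<lineage>"},
#'   the target named by any member of the destination group) and
#'   \code{rationale}.
#' @return The updated \code{lineagePartition}; the overrides log
#'   accumulates.
#' @examples
#' p <- clusterLineages(data.frame(cladeA = "F", cladeB = "H", mean = 0.025))
#' applyOverrides(p, data.frame(lineage = "F", action = "split_out",
#'   rationale = "short 16S fragment deflates the F-H distance"))
#' @export
applyOverrides <- function(partition, overrides) {
  stopifnot(inherits(partition, "lineagePartition"))
  if (is.null(overrides) || nrow(overrides) == 0L) return(partition)
  groups <- partition$groups
  for (r in seq_len(nrow(overrides))) {
    lin <- as.character(overrides$lineage[r])
    act <- as.character(overrides$action[r])
    gi <- which(vapply(groups, function(g) lin %in% g, logical(1)))
    if (!length(gi)) stop("unknown lineage in override: ", lin)
    if (act == "split_out") {
      if (length(groups[[gi]]) == 1L) {
        warning("split_out of already-singleton lineage ", lin, ": no-op")
      } else {
        groups[[gi]] <- setdiff(groups[[gi]], lin)
        groups[[length(groups) + 1L]] <- lin
      }
    } else if (startsWith(act, "merge_into:")) {
      target <- sub("^merge_into:", "", act)
      ti <- which(vapply(groups, function(g) target %in% g, logical(1)))
      if (!length(ti)) stop("unknown target group for override: ", target)
      if (ti != gi) {
        groups[[ti]] <- sort(unique(c(groups[[ti]], lin)))
        groups[[gi]] <- setdiff(groups[[gi]], lin)
      }
    } else {
      stop("unknown override action: ", act)
    }
    groups <- groups[lengths(groups) > 0L]
  }
  groups <- lapply(groups, sort)
  groups <- groups[order(vapply(groups, `[`, character(1), 1L))]
  partition$groups <- groups
  partition$overrides <- rbind(partition$overrides,
                               overrides[, c("lineage", "action", "rationale")])
  partition
}

#' Integrate non-genetic evidence into candidate-species verdicts
#'
#' Applies the confirmed/unconfirmed candidate-species rules to each
#' genetically distinct group: Confirmed Candidate Species (CCS) when
#' genetic divergence covaries with bioacoustic or morphological
#' distinctness; Unconfirmed Candidate Species (UCS) when both non-genetic
#' character sets are unavailable; Deep Conspecific Lineage (DCL) when at
#' least one is available but none is distinct.  Groups holding several
#' merged lineages are assessed as one unit from their pooled evidence;
#' their non-representative members are reported \code{not_candidate}.
#'
#' @param partition A \code{lineagePartition}.
#' @param evidence data.frame with columns \code{lineage},
#'   \code{acoustic_status}, \code{morpho_status}, statuses in
#'   \code{distinct}, \code{not_distinct}, \code{unavailable}; every
#'   lineage in the partition must have a row.
#' @return List of class \code{delimitationResult}: \code{groups},
#'   \code{groupStatus} (one row per group: members, verdict),
#'   \code{lineageStatus} (named vector over lineages),
#'   \code{overrides} carried over from the partition.
#' @export
integrateEvidence <- function(partition, evidence) {
  stopifnot(inherits(partition, "lineagePartition"))
  lineages <- unlist(partition$groups)
  missing <- setdiff(lineages, evidence$lineage)
  if (length(missing))
    stop("lineage(s) missing from the evidence table: ",
         paste(missing, collapse = ", "))
  ok <- c("distinct", "not_distinct", "unavailable")
  if (!all(evidence$acoustic_status %in% ok) ||
      !all(evidence$morpho_status %in% ok))
    stop("evidence statuses must be one of: ", paste(ok, collapse = ", "))
  verdict <- function(members) {
    ev <- evidence[evidence$lineage %in% members, , drop = FALSE]
    st <- c(ev$acoustic_status, ev$morpho_status)
    if (any(st == "distinct")) "CCS"
    else if (all(st == "unavailable")) "UCS"
    else "DCL"
  }
  groups <- partition$groups
  gs <- data.frame(
    group = vapply(groups, paste, character(1), collapse = "+"),
    nLineages = lengths(groups),
    status = vapply(groups, verdict, character(1)),
    stringsAsFactors = FALSE)
  lineageStatus <- stats::setNames(rep("not_candidate", length(lineages)),
                                   lineages)
  for (i in seq_along(groups))
    lineageStatus[groups[[i]][1L]] <- gs$status[i]
  structure(list(groups = groups, groupStatus = gs,
                 lineageStatus = lineageStatus,
                 overrides = partition$overrides),
            class = "delimitationResult")
}

#' @export
print.delimitationResult <- function(x, ...) {
  tab <- table(factor(x$groupStatus$status, levels = c("CCS", "UCS", "DCL")))
  cat(sprintf(
    "Delimitation: %d candidate unit(s) -- %d CCS, %d UCS, %d DCL\n",
    nrow(x$groupStatus), tab["CCS"], tab["UCS"], tab["DCL"]))
  for (i in seq_len(nrow(x$groupStatus)))
    cat(sprintf("  %-12s %s\n", x$groupStatus$group[i], x$groupStatus$status[i]))
  if (nrow(x$overrides)) {
    cat("Overrides:\n")
    for (r in seq_len(nrow(x$overrides)))
      cat(sprintf("  %s %s: %s\n", x$overrides$action[r],
                  x$overrides$lineage[r], x$overrides$rationale[r]))
  }
  invisible(x)
}

#' Read a per-lineage evidence table
#'
#' Delimited text with columns \code{lineage}, \code{acoustic_status},
#' \code{morpho_status}.
#'
#' @param path Path to the file.
#' @return data.frame suitable for [integrateEvidence()].
#' @export
readEvidenceTable <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("lineage", "acoustic_status", "morpho_status")
  if (!all(need %in% names(df)))
    stop("evidence table must have columns: ", paste(need, collapse = ", "))
  df
}
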