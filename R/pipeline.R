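#' Published reference tables shipped with the package
#'
#' Small CSVs of published summary values for the nine mtDNA clades
#' (A--I) of the \emph{D. leucophyllatus--triangulum} complex, used to
#' calibrate the synthetic-data generator and as worked-example inputs:
#' \code{"distances"} (clade-pair 16S p-distance summaries),
#' \code{"svl"} (male snout--vent length summaries), \code{"calls"}
#' (advertisement-call parameters), \code{"evidence"} (acoustic and
#' morphological evidence availability per lineage), \code{"areas"}
#' (range polygon areas and degraded areas, km2).
#'
#' @param which One of \code{"distances"}, \code{"svl"}, \code{"calls"},
#'   \code{"evidence"}, \code{"areas"}.
#' @return data.frame.
#' @examples
#' head(referenceTable("distances"))
#' @export
referenceTable <- function(which = c("distances", "svl", "calls",
                                     "evidence", "areas")) {
  which <- match.arg(which)
  file <- switch(which,
    distances = "clade_p_distances.csv",
    svl = "clade_svl_males.csv",
    calls = "advertisement_call_params.csv",
    evidence = "clade_evidence.csv",
    areas = "range_areas.csv")
  utils::read.csv(system.file("extdata", file, package = "hylidDelim",
                              mustWork = TRUE), stringsAsFactors = FALSE)
}

#' Build a call specification from published call parameters
#'
#' Converts one row of the advertisement-call parameter table into a
#' [CallSpec-class]: one Type I note whose pulse period is
#' \code{typeI_duration_s / typeI_pulses}, followed by
#' \code{round(n_notes) - 1} Type II notes, with the published inter-note
#' distance and mean dominant frequency as the gap and carrier.
#'
#' @param params One-row data.frame with the columns of
#'   \code{referenceTable("calls")}.
#' @param sampleRateHz Sampling rate (default 44100).
#' @return A [CallSpec-class].
#' @examples
#' calls <- referenceTable("calls")
#' callSpecFromParams(calls[calls$clade == "B", ])
#' @export
callSpecFromParams <- function(params, sampleRateHz = 44100) {
  stopifnot(nrow(params) == 1L)
  nI <- max(1L, round(params$typeI_pulses))
  nPulses <- nI
  periods <- params$typeI_duration_s / nI
  amps <- 1
  nTypeII <- max(0L, round(params$n_notes) - 1L)
  if (nTypeII > 0L && !is.na(params$typeII_pulses) &&
      round(params$typeII_pulses) >= 1L) {
    nII <- round(params$typeII_pulses)
    nPulses <- c(nPulses, rep(nII, nTypeII))
    periods <- c(periods, rep(params$typeII_duration_s / nII, nTypeII))
    amps <- c(amps, rep(0.8, nTypeII))
  }
  gap <- if (!is.na(params$inter_note_s) && params$inter_note_s > 0)
    params$inter_note_s else 0.046
  callSpec(nPulses = nPulses, pulsePeriodS = periods, interNoteGapS = gap,
           carrierHz = params$dominant_freq_hz,
           sampleRateHz = sampleRateHz, amplitudes = amps)
}

#' Clade simulation specs calibrated to the published distance table
#'
#' Fits per-clade stem divergences by least squares so that the expected
#' inter-clade p-distances of the simulated alignment,
#' \code{jcExpectedP(stem_i + stem_j + tip_i + tip_j)}, match the
#' published clade-pair means as closely as a star phylogeny permits.
#' Tip divergences come from the published intra-clade means via
#' \code{jcDivergence(intra) / 2}.
#'
#' @param distances Clade-pair summary data.frame (defaults to the
#'   shipped reference table).
#' @param nTips Tips per clade (default 3).
#' @return List with \code{specs} (data.frame of [cladeSimSpec()] rows)
#'   and \code{expected} (data.frame of expected pairwise p-distances
#'   per clade pair under the fitted model).
#' @export
calibratedCladeSpecs <- function(distances = referenceTable("distances"),
                                 nTips = 3L) {
  inter <- distances[distances$cladeA != distances$cladeB, ]
  intra <- distances[distances$cladeA == distances$cladeB, ]
  labs <- sort(unique(c(inter$cladeA, inter$cladeB)))
  tips <- stats::setNames(rep(0.001, length(labs)), labs)
  for (i in seq_len(nrow(intra))) {
    if (!is.na(intra$mean[i]) && intra$mean[i] > 0)
      tips[intra$cladeA[i]] <- jcDivergence(intra$mean[i]) / 2
  }
  # d_ij - tip_i - tip_j ~ stem_i + stem_j, solved by least squares
  A <- matrix(0, nrow(inter), length(labs), dimnames = list(NULL, labs))
  b <- numeric(nrow(inter))
  for (i in seq_len(nrow(inter))) {
    A[i, inter$cladeA[i]] <- 1
    A[i, inter$cladeB[i]] <- 1
    b[i] <- jcDivergence(inter$mean[i]) -
      tips[inter$cladeA[i]] - tips[inter$cladeB[i]]
  }
  stems <- stats::setNames(pmax(as.numeric(qr.solve(A, b)), 0), labs)
  specs <- do.call(rbind, lapply(labs, function(l)
    cladeSimSpec(l, nTips, stems[[l]], tips[[l]])))
  expected <- inter[, c("cladeA", "cladeB")]
  expected$expectedP <- jcExpectedP(
    stems[inter$cladeA] + stems[inter$cladeB] +
      tips[inter$cladeA] + tips[inter$cladeB])
  list(specs = specs, expected = expected)
}

#' Generate a deterministic synthetic fixture set
#'
#' Writes, under \code{dir}: a 9-lineage alignment calibrated to the
#' published clade-pair divergences (FASTA wrapped at 80 columns, plus a
#' two-column clade map), per-lineage synthetic advertisement calls
#' (16-bit PCM WAV) built from the published call parameters, per-clade
#' SVL samples drawn from the published summaries, toy occurrence
#' clouds, and a copy of the evidence table.  Byte-identical for a fixed
#' seed.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param seqLength Alignment length in sites (default 1200).
#' @param nTips Tips per clade (default 3).
#' @return Invisibly, a list of the written paths.
#' @export
makeFixtures <- function(dir, seed = 1L, seqLength = 1200L, nTips = 3L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  cal <- calibratedCladeSpecs(nTips = nTips)
  sim <- simulateAlignment(cal$specs, seqLength, seed = seed)
  fasta <- file.path(dir, "alignment.fasta")
  Biostrings::writeXStringSet(sim$alignment, fasta, width = 80L)
  cladeMap <- file.path(dir, "clade_map.csv")
  utils::write.table(data.frame(id = names(sim$clades), clade = sim$clades),
                     cladeMap, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  svlTab <- referenceTable("svl")
  svl <- do.call(rbind, lapply(seq_len(nrow(svlTab)), function(i)
    data.frame(clade = svlTab$clade[i],
               svl_mm = round(sampleSvl(svlTab$mean[i], svlTab$sd[i],
                                        svlTab$n[i], seed = seed + i), 2))))
  svlPath <- file.path(dir, "svl.csv")
  utils::write.csv(svl, svlPath, row.names = FALSE, quote = FALSE)
  callTab <- referenceTable("calls")
  callDir <- file.path(dir, "calls")
  dir.create(callDir, showWarnings = FALSE)
  wavPaths <- character(0)
  for (i in seq_len(nrow(callTab))) {
    spec <- callSpecFromParams(callTab[i, ])
    w <- synthesizeCall(spec, seed = seed + 100L + i)
    p <- file.path(callDir, sprintf("clade_%s.wav", callTab$clade[i]))
    writeWav(w, p)
    wavPaths <- c(wavPaths, p)
  }
  occDir <- file.path(dir, "occurrences")
  dir.create(occDir, showWarnings = FALSE)
  centers <- data.frame(
    clade = c("A", "B", "C", "D", "E", "F", "G", "H", "I"),
    lon = c(-63.7, -53.1, -76.4, -70.5, -71.3, -52.5, -52.0, -74.0, -73.5),
    lat = c(-16.4, 4.0, -0.9, -11.0, -12.6, -2.5, -3.5, -4.5, -12.9),
    n = c(12L, 20L, 30L, 8L, 6L, 4L, 5L, 25L, 3L))
  occPaths <- character(0)
  for (i in seq_len(nrow(centers))) {
    occ <- simulateOccurrences(centers$lon[i], centers$lat[i], centers$n[i],
                               spreadDeg = 1.5, seed = seed + 200L + i)
    occ <- round(occ, 4)
    p <- file.path(occDir, sprintf("clade_%s.csv", centers$clade[i]))
    utils::write.csv(occ, p, row.names = FALSE, quote = FALSE)
    occPaths <- c(occPaths, p)
  }
  evPath <- file.path(dir, "evidence.csv")
  utils::write.csv(referenceTable("evidence"), evPath, row.names = FALSE,
                   quote = FALSE)
  invisible(list(alignment = fasta, cladeMap = cladeMap, svl = svlPath,
                 calls = wavPaths, occurrences = occPaths,
                 evidence = evPath, expected = cal$expected))
}

#' Read a pipeline run configuration
#'
#' YAML key-value file with input paths (\code{alignment},
#' \code{clade_map}, \code{svl}, \code{calls_dir}, \code{evidence},
#' \code{occurrences_dir}), the delimitation \code{threshold}, optional
#' \code{overrides} entries (lineage/action/rationale), a \code{seed}
#' and an \code{out_dir}.  Unset inputs make the corresponding stage
#' report unavailable rather than fail.
#'
#' @param path Path to the YAML file.
#' @return Named list (class \code{runConfig}).
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(threshold = 0.03, seed = 1L, out_dir = "delim-output")
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  for (nm in c("alignment", "clade_map", "svl", "evidence")) {
    if (!is.null(cfg[[nm]]) && !file.exists(cfg[[nm]]))
      stop("configured input does not exist: ", nm, " = ", cfg[[nm]])
  }
  structure(cfg, class = "runConfig")
}

#' Run the integrative delimitation pipeline
#'
#' Executes the stages that the configured inputs permit -- genetic
#' distances and clustering, evidence integration, call feature
#' extraction and PCA, SVL summaries and Welch tests, range reports --
#' and writes each stage's table plus one combined text report and a
#' manifest (config, seed, package version) to the output directory.
#' Missing inputs skip their stage with a logged notice; in particular,
#' absent audio marks the acoustic evidence unavailable, which feeds the
#' unconfirmed-candidate-species rule.
#'
#' @param config A \code{runConfig} (from [readRunConfig()]) or an
#'   equivalent named list.
#' @return Invisibly, a list with the per-stage results and the paths
#'   written.
#' @export
runPipeline <- function(config) {
  cfg <- unclass(config)
  outDir <- cfg$out_dir %||% "delim-output"
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  notices <- character(0)
  note <- function(msg) {
    notices <<- c(notices, msg)
    message(msg)
  }
  results <- list()
  report <- c("Integrative species delimitation report", "")

  # --- genetics -> delimitation -----------------------------------------
  if (!is.null(cfg$alignment) && !is.null(cfg$clade_map)) {
    aln <- Biostrings::readDNAStringSet(cfg$alignment)
    if (!length(aln)) stop("alignment is empty: ", cfg$alignment)
    clades <- readCladeMap(cfg$clade_map)
    dm <- pairwisePDistance(aln, minSites = cfg$min_sites %||% 200)
    utils::write.csv(distances(dm), file.path(outDir, "distance_matrix.csv"))
    summ <- cladePairSummary(dm, clades)
    utils::write.csv(summ, file.path(outDir, "clade_summary.csv"),
                     row.names = FALSE)
    summaryMatrixTable(summ, file.path(outDir, "clade_summary_matrix.csv"))
    inter <- summ[summ$cladeA != summ$cladeB, ]
    inter$category <- as.character(classifyDivergence(inter$mean))
    utils::write.csv(inter, file.path(outDir, "divergence_categories.csv"),
                     row.names = FALSE)
    part <- clusterLineages(summ, threshold = cfg$threshold %||% 0.03)
    if (!is.null(cfg$overrides)) {
      ov <- do.call(rbind, lapply(cfg$overrides, as.data.frame))
      part <- applyOverrides(part, ov)
    }
    results$distances <- dm
    results$summary <- summ
    results$partition <- part
    report <- c(report,
      sprintf("Genetic distances: %d sequences, %d clades.",
              nrow(distances(dm)), length(unique(clades))),
      sprintf("Threshold clustering at %.3g gives %d candidate group(s).",
              cfg$threshold %||% 0.03, length(part$groups)))
    if (!is.null(cfg$evidence)) {
      ev <- readEvidenceTable(cfg$evidence)
      delim <- integrateEvidence(part, ev)
      utils::write.csv(delim$groupStatus,
                       file.path(outDir, "delimitation.csv"),
                       row.names = FALSE)
      results$delimitation <- delim
      tab <- table(factor(delim$groupStatus$status,
                          levels = c("CCS", "UCS", "DCL")))
      report <- c(report, sprintf(
        "Evidence integration: %d CCS, %d UCS, %d DCL.",
        tab[["CCS"]], tab[["UCS"]], tab[["DCL"]]))
    } else {
      note("no evidence table configured; delimitation verdicts skipped")
    }
  } else {
    note("alignment/clade map not configured; genetic stage skipped")
  }

  # --- acoustics -> stats ------------------------------------------------
  wavs <- if (!is.null(cfg$calls_dir))
    list.files(cfg$calls_dir, "\\.wav$", full.names = TRUE) else character(0)
  if (length(wavs)) {
    feats <- extractCallFeatureTable(wavs)
    utils::write.csv(feats, file.path(outDir, "call_features.csv"),
                     row.names = FALSE)
    results$callFeatures <- feats
    report <- c(report, sprintf(
      "Acoustics: %d call(s) analysed (%d advertisement).",
      nrow(feats), sum(feats$call_type == "advertisement")))
    vars <- c("typeI_duration_s", "n_pulses_typeI", "rise_time_typeI_s",
              "freq_bandwidth_hz", "dominant_freq_hz")
    adv <- feats[feats$call_type == "advertisement" &
                   stats::complete.cases(feats[, vars]), ]
    if (nrow(adv) >= 3L) {
      pca <- tryCatch(correlationPca(adv[, vars]), error = function(e) NULL)
      if (!is.null(pca)) {
        utils::write.csv(cbind(variable = rownames(pca@loadings),
                               as.data.frame(pca@loadings)),
                         file.path(outDir, "pca_loadings.csv"),
                         row.names = FALSE)
        utils::write.csv(
          data.frame(component = seq_along(pca@eigenvalues),
                     eigenvalue = pca@eigenvalues,
                     percent_variance = pca@percentVariance),
          file.path(outDir, "pca_eigenvalues.csv"), row.names = FALSE)
        if (pca@retained > 0L)
          utils::write.csv(cbind(file = adv$file,
                                 as.data.frame(pca@scores)),
                           file.path(outDir, "pca_scores.csv"),
                           row.names = FALSE)
        results$pca <- pca
        report <- c(report, sprintf(
          "Call PCA: %d component(s) retained (eigenvalue > 1), %.1f%% of variance.",
          pca@retained,
          sum(pca@percentVariance[seq_len(max(pca@retained, 1L))])))
      }
    }
  } else {
    note("no call recordings configured; acoustic stage marked unavailable")
    report <- c(report, "Acoustics: unavailable.")
  }

  # --- morphology --------------------------------------------------------
  if (!is.null(cfg$svl)) {
    svl <- utils::read.csv(cfg$svl, stringsAsFactors = FALSE)
    gs <- summarizeGroups(svl[[2]], svl[[1]])
    utils::write.csv(gs, file.path(outDir, "svl_summary.csv"),
                     row.names = FALSE)
    tests <- list()
    for (a in seq_len(nrow(gs) - 1L)) {
      for (b in seq(a + 1L, nrow(gs))) {
        if (gs$n[a] < 2L || gs$n[b] < 2L) next
        wt <- welchFromSummary(gs$mean[a], gs$sd[a], gs$n[a],
                               gs$mean[b], gs$sd[b], gs$n[b])
        tests[[length(tests) + 1L]] <- data.frame(
          groupA = gs$group[a], groupB = gs$group[b],
          t = wt$t, df = wt$dfRounded, p = wt$p)
      }
    }
    svlTests <- do.call(rbind, tests)
    utils::write.csv(svlTests, file.path(outDir, "svl_tests.csv"),
                     row.names = FALSE)
    results$svlSummary <- gs
    results$svlTests <- svlTests
    report <- c(report, sprintf(
      "Morphometrics: SVL summarised for %d group(s); %d pairwise Welch test(s).",
      nrow(gs), if (is.null(svlTests)) 0L else nrow(svlTests)))
  } else {
    note("no specimen table configured; morphometric stage skipped")
  }

  # --- ranges ------------------------------------------------------------
  occs <- if (!is.null(cfg$occurrences_dir))
    list.files(cfg$occurrences_dir, "\\.csv$", full.names = TRUE)
  else character(0)
  if (length(occs)) {
    rr <- lapply(occs, function(p) {
      r <- rangeReport(readOccurrences(p))
      c(list(file = basename(p)), unclass(r))
    })
    ranges <- do.call(rbind, lapply(rr, function(x)
      data.frame(file = x$file, area_km2 = x$areaKm2,
                 n_localities = x$nLocalities,
                 suggested_category = x$suggestedCategory)))
    jsonlite::write_json(rr, file.path(outDir, "range_reports.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    results$ranges <- ranges
    report <- c(report, sprintf(
      "Ranges: %d occurrence set(s); categories: %s.", nrow(ranges),
      paste(sprintf("%s=%s", sub("\\.csv$", "", ranges$file),
                    ranges$suggested_category), collapse = ", ")))
  } else {
    note("no occurrence files configured; range stage skipped")
  }

  if (length(notices)) report <- c(report, "", "Notices:", paste(" -", notices))
  writeLines(report, file.path(outDir, "report.txt"))
  manifest <- list(
    package = "hylidDelim",
    version = as.character(utils::packageVersion("hylidDelim")),
    seed = cfg$seed %||% NA,
    config = cfg[setdiff(names(cfg), "out_dir")])
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$notices <- notices
  results$outDir <- outDir
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
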