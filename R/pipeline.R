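# End-to-end study orchestration: manifest -> uptake-matched frame
# bookkeeping -> SUV/SUL conversion -> metric extraction -> paired
# repeatability tables, session comparisons, pairwise |%-delta|
# comparisons under BH FDR control, and Bland-Altman plot data. Every
# summary row is reproducible by calling the repeatability functions on
# the emitted per-subject metric table; there is no hidden state.

.DEFAULT_METRICS <- list(
  activity_Bq_per_mL = c("suv_max", "suv_mean", "suv_median", "suv_peak",
                         "sul_peak", "metabolic_tumor_volume_mL",
                         "total_lesion_glycolysis_g"),
  SUV_g_per_mL = c("suv_max", "suv_mean", "suv_median", "suv_peak",
                   "metabolic_tumor_volume_mL",
                   "total_lesion_glycolysis_g"),
  SUL_g_per_mL = c("sul_peak", "sul_max"),
  `ADC_1e-3_mm2_per_s` = c("adc_median", "adc_mean", "adc_trough",
                           "diffusional_tumor_volume_mL"))

#' Assemble a study configuration
#'
#' @param manifest path to a `manifest.json` written by
#'   [generatePairedStudy()] (or an equivalent list already in memory).
#' @param baseDir directory that relative paths in the manifest resolve
#'   against; defaults to the manifest's directory.
#' @param metrics named list mapping value kinds to metric vectors;
#'   defaults cover every metric supported per kind (activity volumes are
#'   converted to SUV and SUL first, so SUV/SUL metrics apply).
#' @param wcvDivisor `"sqrt2"` or `"2"` (see [repeatabilitySummary()]).
#' @param fdrQ Benjamini-Hochberg false-discovery rate for the pairwise
#'   repeatability comparisons (default 0.05).
#' @param comparisonPlan `data.frame` with columns `metricA`,
#'   `modalityA`, `metricB`, `modalityB`, `test` (`"mannwhitney"` or
#'   `"wilcoxon"`): which pairs of per-subject |%-delta| distributions to
#'   compare. Default: SUV_max and SUL_peak across modalities
#'   (Mann-Whitney) and ADC_median vs SUV_max within PET/MRI, when both
#'   modalities are present.
#' @param reconLabel free-form reconstruction label carried into tables
#'   (metadata only).
#' @return A validated config list for [runStudy()].
#' @export
studyConfig <- function(manifest, baseDir = NULL, metrics = NULL,
                        wcvDivisor = c("sqrt2", "2"), fdrQ = 0.05,
                        comparisonPlan = NULL, reconLabel = "OSEM") {
  wcvDivisor <- match.arg(wcvDivisor)
  if (is.character(manifest)) {
    if (is.null(baseDir)) baseDir <- dirname(manifest)
    manifest <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  }
  if (is.null(baseDir)) baseDir <- "."
  if (is.null(metrics)) metrics <- .DEFAULT_METRICS
  mods <- unlist(manifest$modalities)
  if (is.null(comparisonPlan)) {
    comparisonPlan <- data.frame(metricA = character(0),
                                 modalityA = character(0),
                                 metricB = character(0),
                                 modalityB = character(0),
                                 test = character(0))
    if (all(c("PETCT", "PETMR") %in% mods)) {
      comparisonPlan <- data.frame(
        metricA = c("suv_max", "sul_peak", "adc_median"),
        modalityA = c("PETCT", "PETCT", "PETMR"),
        metricB = c("suv_max", "sul_peak", "suv_max"),
        modalityB = c("PETMR", "PETMR", "PETMR"),
        test = "mannwhitney")
    }
  }
  stopifnot(all(c("metricA", "modalityA", "metricB", "modalityB",
                  "test") %in% names(comparisonPlan)))
  badm <- setdiff(c(comparisonPlan$metricA, comparisonPlan$metricB),
                  names(.METRIC_KINDS))
  if (length(badm))
    stop("comparison plan references undefined metric(s): ",
         paste(unique(badm), collapse = ", "))
  list(manifest = manifest, baseDir = baseDir, metrics = metrics,
       wcvDivisor = wcvDivisor, fdrQ = fdrQ,
       comparisonPlan = comparisonPlan, reconLabel = reconLabel)
}

.entryDf <- function(entries) {
  do.call(rbind, lapply(entries, function(e) data.frame(
    subject_id = e$subject_id, session = e$session,
    modality = e$modality, value_kind = e$value_kind,
    volume = e$volume, mask = e$mask,
    subject_record = e$subject_record,
    window_start = e$window$start_min,
    window_duration = e$window$duration_min,
    stringsAsFactors = FALSE)))
}

#' Run a complete test-retest repeatability study
#'
#' Loads every (subject, session, modality) volume + mask listed in the
#' manifest, converts PET activity volumes to SUV and SUL at the matched
#' frame start (latest-overlap policy for PET/CT, earliest for PET/MRI,
#' so both sessions share one real uptake interval per modality),
#' extracts the configured metrics, and computes the full repeatability
#' battery. Subjects missing one session of a (modality, kind) pairing
#' are excluded from that pairing with a logged reason.
#'
#' @param config from [studyConfig()].
#' @param outDir optional directory: writes `metrics.csv`,
#'   `repeatability.csv`, `session_comparisons.csv`, `comparisons.csv`,
#'   `bland_altman.csv` and `uptake_report.csv`.
#' @return A list:
#'   \describe{
#'     \item{metricTable}{per (subject, session, modality, kind, metric)
#'       values.}
#'     \item{sessionComparisons}{Wilcoxon signed-rank of session 1 vs 2
#'       per metric group.}
#'     \item{repeatability}{one [repeatabilitySummary()] row per metric x
#'       modality x frame duration.}
#'     \item{comparisons}{the pairwise mean |%-delta| comparison table
#'       with BH-adjusted significance and the realized p cutoff.}
#'     \item{blandAltman}{per-group Bland-Altman plot data.}
#'     \item{uptake}{per-modality matched-interval audit.}
#'     \item{exclusions}{subject/rule log.}
#'     \item{pairs}{the named list of paired-measurement data frames the
#'       summaries were computed from.}
#'   }
#' @export
runStudy <- function(config, outDir = NULL) {
  man <- config$manifest
  entries <- .entryDf(man$entries)
  frameDur <- man$frame_duration_min %||% 5
  recon <- config$reconLabel

  # --- exclusions: need both sessions per (subject, modality, kind)
  key <- interaction(entries$subject_id, entries$modality,
                     entries$value_kind, drop = TRUE)
  exclusions <- data.frame(subject_id = character(0),
                           modality = character(0),
                           value_kind = character(0), rule = character(0))
  keep <- rep(TRUE, nrow(entries))
  for (k in levels(key)) {
    sel <- key == k
    ses <- sort(unique(entries$session[sel]))
    if (!identical(ses, 1:2)) {
      keep[sel] <- FALSE
      exclusions <- rbind(exclusions, data.frame(
        subject_id = entries$subject_id[sel][1],
        modality = entries$modality[sel][1],
        value_kind = entries$value_kind[sel][1],
        rule = sprintf("missing session %d", setdiff(1:2, ses)[1])))
    }
  }
  if (nrow(exclusions))
    message("excluded ", nrow(exclusions),
            " subject-modality pairing(s): ",
            paste(sprintf("%s/%s/%s (%s)", exclusions$subject_id,
                          exclusions$modality, exclusions$value_kind,
                          exclusions$rule), collapse = "; "))
  entries <- entries[keep, , drop = FALSE]
  if (nrow(entries) == 0L) stop("no complete subject pairings left")

  # --- uptake-matched frames per (subject, modality) PET pairing
  refTimes <- list()   # key -> c(refTime session1, session2)
  intervalsByMod <- list()
  petRows <- entries$value_kind == "activity_Bq_per_mL"
  pkeys <- unique(entries[petRows, c("subject_id", "modality")])
  if (nrow(pkeys)) for (r in seq_len(nrow(pkeys))) {
    sel <- entries$subject_id == pkeys$subject_id[r] &
           entries$modality == pkeys$modality[r] & petRows
    e1 <- entries[sel & entries$session == 1, ]
    e2 <- entries[sel & entries$session == 2, ]
    policy <- if (pkeys$modality[r] == "PETCT") "latest" else "earliest"
    iv <- matchedInterval(
      acquisitionWindow(e1$window_start, e1$window_duration),
      acquisitionWindow(e2$window_start, e2$window_duration),
      frameDur, policy)
    refTimes[[paste(pkeys$subject_id[r], pkeys$modality[r])]] <-
      rep(iv$uptakeInterval[1], 2)
    intervalsByMod[[pkeys$modality[r]]] <-
      c(intervalsByMod[[pkeys$modality[r]]], list(iv))
  }
  uptake <- do.call(rbind, lapply(names(intervalsByMod), function(mod) {
    rp <- uptakeReport(intervalsByMod[[mod]])
    data.frame(modality = mod, n = rp$n, anchor = rp$anchor,
               mean_min = rp$meanMin, range_lo = rp$rangeMin[1],
               range_hi = rp$rangeMin[2])
  }))

  # --- metric extraction
  rows <- list()
  for (r in seq_len(nrow(entries))) {
    e <- entries[r, ]
    vol <- readVolume(file.path(config$baseDir, e$volume), e$value_kind)
    msk <- readMask(file.path(config$baseDir, e$mask), vol)
    wanted <- config$metrics[[e$value_kind]]
    if (is.null(wanted)) next
    sets <- list()
    if (e$value_kind == "activity_Bq_per_mL") {
      rec <- readSubjectRecord(file.path(config$baseDir,
                                         e$subject_record))
      refT <- refTimes[[paste(e$subject_id, e$modality)]][e$session]
      suv <- activityToSUV(vol, rec, referenceTimeMin = refT)
      sul <- suvToSUL(suv, rec)
      wantSUV <- intersect(wanted, supportedMetrics("SUV_g_per_mL"))
      wantSUL <- intersect(wanted, supportedMetrics("SUL_g_per_mL"))
      wantSUL <- setdiff(wantSUL, wantSUV)  # MTV/TLG from the SUV volume
      if (length(wantSUV))
        sets <- c(sets, list(extractMetricSet(suv, msk, wantSUV)))
      if (length(wantSUL))
        sets <- c(sets, list(extractMetricSet(sul, msk, wantSUL)))
    } else {
      sets <- list(extractMetricSet(vol, msk, wanted))
    }
    for (ms in sets) {
      v <- metricValues(ms)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = e$subject_id, session = e$session,
        modality = e$modality, value_kind = e$value_kind,
        frame_duration_min = frameDur, recon = recon,
        metric = names(v), value = unname(v), stringsAsFactors = FALSE)
    }
  }
  metricTable <- do.call(rbind, rows)
  rownames(metricTable) <- NULL

  # --- pair up sessions per (modality, kind, metric)
  pairsList <- list()
  grp <- unique(metricTable[, c("modality", "value_kind", "metric")])
  for (g in seq_len(nrow(grp))) {
    sel <- metricTable$modality == grp$modality[g] &
           metricTable$value_kind == grp$value_kind[g] &
           metricTable$metric == grp$metric[g]
    t1 <- metricTable[sel & metricTable$session == 1, ]
    t2 <- metricTable[sel & metricTable$session == 2, ]
    common <- intersect(t1$subject_id, t2$subject_id)
    if (length(common) < 2L) next
    pm <- pairedMeasurements(
      common, t1$value[match(common, t1$subject_id)],
      t2$value[match(common, t2$subject_id)],
      metric = grp$metric[g])
    pairsList[[paste(grp$modality[g], grp$metric[g], sep = ".")]] <- pm
  }

  # --- session 1 vs 2 comparison and repeatability summaries
  sessionComparisons <- do.call(rbind, lapply(names(pairsList),
    function(nm) {
      pm <- pairsList[[nm]]
      wt <- wilcoxonSignedRank(pm$m1, pm$m2)
      data.frame(group = nm, metric = attr(pm, "metric"), n = nrow(pm),
                 mean_s1 = mean(pm$m1), mean_s2 = mean(pm$m2),
                 statistic = wt$statistic, p = wt$p,
                 stringsAsFactors = FALSE)
    }))
  repeatability <- do.call(rbind, lapply(names(pairsList), function(nm) {
    pm <- pairsList[[nm]]
    df <- as.data.frame(repeatabilitySummary(pm, config$wcvDivisor))
    cbind(data.frame(group = nm,
                     modality = sub("\\..*$", "", nm),
                     frame_duration_min = frameDur, recon = recon),
          df)
  }))

  # --- pairwise mean |%-delta| comparisons under BH FDR control
  plan <- config$comparisonPlan
  comparisons <- NULL
  if (nrow(plan)) {
    cmpRows <- list()
    for (i in seq_len(nrow(plan))) {
      ka <- paste(plan$modalityA[i], plan$metricA[i], sep = ".")
      kb <- paste(plan$modalityB[i], plan$metricB[i], sep = ".")
      pa <- pairsList[[ka]]; pb <- pairsList[[kb]]
      if (is.null(pa) || is.null(pb))
        stop("comparison plan references an unavailable group: ",
             if (is.null(pa)) ka else kb)
      da <- abs(percentDifference(pa$m1, pa$m2))
      db <- abs(percentDifference(pb$m1, pb$m2))
      if (plan$test[i] == "wilcoxon") {
        common <- intersect(pa$subject, pb$subject)
        tst <- wilcoxonSignedRank(da[match(common, pa$subject)],
                                  db[match(common, pb$subject)])
      } else {
        tst <- mannWhitneyU(da, db)
      }
      cmpRows[[i]] <- data.frame(
        groupA = ka, groupB = kb, test = plan$test[i],
        mean_abs_pd_A = mean(da), mean_abs_pd_B = mean(db),
        statistic = tst$statistic, p = tst$p, stringsAsFactors = FALSE)
    }
    comparisons <- do.call(rbind, cmpRows)
    bh <- benjaminiHochberg(comparisons$p, config$fdrQ)
    comparisons$p_adjusted <- bh$adjusted
    comparisons$significant <- bh$reject
    attr(comparisons, "realizedCutoff") <- bh$cutoff
  }

  # --- Bland-Altman plot data
  blandAltman <- do.call(rbind, lapply(names(pairsList), function(nm) {
    pm <- pairsList[[nm]]
    ba <- blandAltmanExport(pm, repeatabilitySummary(pm,
                                                    config$wcvDivisor))
    cbind(group = nm, ba$points,
          mu = ba$lines[["mu"]], sd_lower = ba$lines[["sd_lower"]],
          sd_upper = ba$lines[["sd_upper"]],
          rc_lower = ba$lines[["rc_lower"]],
          rc_upper = ba$lines[["rc_upper"]])
  }))

  result <- list(metricTable = metricTable,
                 sessionComparisons = sessionComparisons,
                 repeatability = repeatability,
                 comparisons = comparisons, blandAltman = blandAltman,
                 uptake = uptake, exclusions = exclusions,
                 pairs = pairsList)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeResultsTable(metricTable, file.path(outDir, "metrics.csv"))
    writeResultsTable(repeatability,
                      file.path(outDir, "repeatability.csv"))
    writeResultsTable(sessionComparisons,
                      file.path(outDir, "session_comparisons.csv"))
    if (!is.null(comparisons))
      writeResultsTable(comparisons, file.path(outDir,
                                               "comparisons.csv"))
    writeResultsTable(blandAltman, file.path(outDir,
                                             "bland_altman.csv"))
    if (!is.null(uptake))
      writeResultsTable(uptake, file.path(outDir, "uptake_report.csv"))
  }
  result
}

#' Bland-Altman plot data for one paired metric
#'
#' Per subject: the pair mean (x) and %-delta (y), plus the reference
#' lines of the plot: the mean %-delta (mu), mu +/- SD (dotted lines) and
#' mu +/- 1.96 SD (the 95% limits of repeatability; their distance from
#' mu is the repeatability coefficient, so upper - lower = 2 RC).
#'
#' @param pairs a [pairedMeasurements()] data frame.
#' @param summary the matching [RepeatabilitySummary-class].
#' @param path optional CSV destination; the file carries the points and
#'   the reference lines (constant columns), so re-reading it supports
#'   identical summary recomputation from `m1`/`m2`.
#' @return A list: `points` (`data.frame`) and `lines` (named numeric:
#'   `mu`, `sd_lower`, `sd_upper`, `rc_lower`, `rc_upper`).
#' @export
blandAltmanExport <- function(pairs, summary, path = NULL) {
  pd <- percentDifference(pairs$m1, pairs$m2)
  points <- data.frame(subject = pairs$subject, m1 = pairs$m1,
                       m2 = pairs$m2, pair_mean = (pairs$m1 + pairs$m2) / 2,
                       pct_delta = pd, stringsAsFactors = FALSE)
  mu <- summary@meanPctDelta
  s <- summary@sdPctDelta
  lines <- c(mu = mu, sd_lower = mu - s, sd_upper = mu + s,
             rc_lower = summary@lor[1], rc_upper = summary@lor[2])
  if (!is.null(path)) {
    out <- cbind(points, as.list(lines))
    writeResultsTable(out, path)
  }
  list(points = points, lines = lines)
}
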