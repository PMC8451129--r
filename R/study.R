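## One simulated subject-timepoint: phantom -> acquisitions -> fits.
## Returns the fitted parameter maps, the ROI labels and the functional
## metrics. Blood T1 inputs of the ECV stage are taken from the fitted
## blood-pool ROI means, so ECV is computed fully end-to-end.
.runSubjectTimepoint <- function(cohort, timepoint, seed, modalities,
                                 overrides) {
  cfg <- do.call(defaultPhantomConfig,
                 c(list(timepoint = timepoint, cohort = cohort,
                        seed = seed), overrides))
  gt <- buildPhantom(cfg)
  myo <- myocardium(gt)
  fitMask <- myo | bloodMask(gt)
  sigma <- cfg@noiseSigma
  maps <- list()
  fun <- list()

  if ("t2" %in% modalities) {
    ser <- simulateMultiEcho(truthMap(gt, "T2"), seed = seed,
                             noiseSigma = sigma * 1000, s0 = 1000)
    maps$T2 <- fitT2Map(ser, myo)
  }
  if ("t1" %in% modalities) {
    pre <- simulateMOLLI(truthMap(gt, "T1native"),
                         defaultInversionTimes("pre"),
                         seed = seed + 1L, noiseSigma = sigma * 1000)
    post <- simulateMOLLI(truthMap(gt, "T1post"),
                          defaultInversionTimes("post"),
                          seed = seed + 2L, noiseSigma = sigma * 1000)
    fitPre <- fitT1Map(pre, fitMask)
    fitPost <- fitT1Map(post, fitMask)
    t1pre <- t1Map(fitPre); t1post <- t1Map(fitPost)
    maps$T1native <- t1pre
    blood <- bloodMask(gt)
    if (any(blood)) {
      ecv <- computeECVMap(t1pre, t1post,
                           bloodT1pre = mean(t1pre[blood], na.rm = TRUE),
                           bloodT1post = mean(t1post[blood], na.rm = TRUE),
                           hematocrit = cfg@hematocrit)
      maps$ECV <- ecvValues(ecv)
    }
  }
  if ("dwi" %in% modalities) {
    tfTrue <- makeTensorField(gt)
    proto <- defaultDiffusionProtocol()
    dwi <- simulateDWI(tfTrue, proto, s0 = 1000, noiseFraction = sigma,
                       seed = seed + 3L)
    tf <- fitDiffusionTensor(dwi, proto, myo)
    met <- tensorMetrics(tf)
    maps$MD <- met$md
    maps$FA <- met$fa
    fr <- lvFrames(gt)
    ha <- helixAngleMap(tf, fr)
    grad <- try(transmuralHAGradient(ha, fr, ahaSegments(gt)),
                silent = TRUE)
    if (!inherits(grad, "try-error")) fun$haGradient <- grad$slope
  }
  if ("lge" %in% modalities && any(truthMap(gt, "scar"))) {
    lge <- simulateLGE(gt, seed = seed + 4L)
    remote <- (ahaSegments(gt) == 8L | ahaSegments(gt) == 9L) & myo
    sc <- segmentScar5SD(lge, myo, remote)
    fun$scarFraction <- sc$scarFraction
  }
  if ("motion" %in% modalities) {
    tc <- simulateContourMotion(gt)
    tor <- torsionFromContours(tc)
    st <- globalStrains(tc)
    vol <- lvVolumes(simulateCavityMasks(gt), cfg@sliceThickness,
                     cfg@sliceGap, cfg@pixelSpacing)
    fun <- c(fun, list(torsion = tor$peak, GRS = st$GRS, GCS = st$GCS,
                       GLS = st$GLS, LVEDV = vol$LVEDV,
                       LVESV = vol$LVESV, SV = vol$SV, LVEF = vol$LVEF))
  }
  ## control phantoms have no infarct ROI; drop it rather than warn per map
  roi <- list(remote = roiLabels(gt) == 1L)
  if (any(roiLabels(gt) == 2L)) roi$infarct <- roiLabels(gt) == 2L
  list(maps = maps, roi = roi, fun = fun)
}

#' Run a whole simulated study
#'
#' Simulates both cohorts over the configured timepoints (phantom,
#' acquisitions, fits, summaries) and computes the study-level statistics:
#' the long region table of fitted ROI means, per-timepoint relative
#' changes (infarct vs remote and vs baseline), the control-vs-remote bias
#' distributions, the functional/structural metric table and the
#' correlation of global longitudinal strain with the septal transmural
#' helix-angle gradient. All outputs are deterministic given the study
#' seed; failed stages are recorded per subject instead of aborting.
#'
#' @param cfg a study configuration from \code{\link{defaultStudyConfig}}.
#' @param outDir optional directory; when given, the region table, the
#'   function table and a run manifest are written as CSV/JSON.
#' @return List of class \code{"StudyReport"}: \code{regionTable},
#'   \code{functionTable}, \code{contrasts}, \code{bias},
#'   \code{correlations}, \code{failures}.
#' @export
runStudy <- function(cfg, outDir = NULL) {
  stopifnot(inherits(cfg, "StudyConfig"))
  subjects <- c(sprintf("ctl%02d", seq_len(cfg$nControl)),
                sprintf("inf%02d", seq_len(cfg$nInfarct)))
  groups <- rep(c("control", "infarct"), c(cfg$nControl, cfg$nInfarct))
  regionRows <- list(); funRows <- list(); failures <- list()
  for (si in seq_along(subjects)) {
    for (ti in seq_along(cfg$timepoints)) {
      tp <- cfg$timepoints[ti]
      seed <- cfg$seed + 97L * si + ti
      res <- try(.runSubjectTimepoint(groups[si], tp, seed,
                                      cfg$modalities, cfg$overrides),
                 silent = TRUE)
      if (inherits(res, "try-error")) {
        failures[[paste(subjects[si], tp, sep = ".")]] <-
          conditionMessage(attr(res, "condition"))
        next
      }
      if (length(res$maps))
        regionRows[[length(regionRows) + 1L]] <-
          summarizeRegions(res$maps, res$roi, subjects[si], groups[si], tp)
      if (length(res$fun))
        funRows[[length(funRows) + 1L]] <- data.frame(
          subject = subjects[si], group = groups[si], timepoint = tp,
          metric = names(res$fun),
          value = unlist(res$fun, use.names = FALSE))
    }
  }
  regionTable <- do.call(rbind, regionRows)
  functionTable <- do.call(rbind, funRows)

  post <- setdiff(cfg$timepoints, "baseline")
  params <- unique(regionTable$parameter)
  contrasts <- list(); bias <- list()
  for (tp in post) for (pm in params) {
    key <- paste(pm, tp, sep = ".")
    contrasts[[paste0(key, ".vs_remote")]] <-
      try(relativeChange(regionTable, pm, tp, "infarct_vs_remote"),
          silent = TRUE)
    if ("baseline" %in% cfg$timepoints)
      contrasts[[paste0(key, ".vs_baseline")]] <-
        try(relativeChange(regionTable, pm, tp, "infarct_vs_baseline"),
            silent = TRUE)
    bias[[key]] <- try(controlRemoteBias(regionTable, pm, tp),
                       silent = TRUE)
  }
  correlations <- list()
  if (!is.null(functionTable)) {
    wide <- tryCatch({
      gls <- functionTable[functionTable$metric == "GLS", ]
      hag <- functionTable[functionTable$metric == "haGradient", ]
      m <- merge(gls, hag, by = c("subject", "timepoint"))
      correlatePairs(m$value.x, m$value.y)
    }, error = function(e) NULL)
    if (!is.null(wide)) correlations$GLS_vs_haGradient <- wide
  }
  report <- structure(list(regionTable = regionTable,
                           functionTable = functionTable,
                           contrasts = contrasts, bias = bias,
                           correlations = correlations,
                           failures = failures, config = cfg),
                      class = "StudyReport")
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    write.csv(regionTable, file.path(outDir, "region_table.csv"),
              row.names = FALSE)
    if (!is.null(functionTable))
      write.csv(functionTable, file.path(outDir, "function_table.csv"),
                row.names = FALSE)
    jsonlite::write_json(
      list(seed = cfg$seed, timepoints = cfg$timepoints,
           nControl = cfg$nControl, nInfarct = cfg$nInfarct,
           modalities = cfg$modalities,
           failures = failures),
      file.path(outDir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  report
}

#' @export
print.StudyReport <- function(x, ...) {
  cat("StudyReport: ", length(unique(x$regionTable$subject)),
      " subjects x ", length(unique(x$regionTable$timepoint)),
      " timepoints; ", nrow(x$regionTable), " region rows, ",
      if (is.null(x$functionTable)) 0L else nrow(x$functionTable),
      " function rows; ", length(x$failures), " failed stage(s)\n",
      sep = "")
  invisible(x)
}
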