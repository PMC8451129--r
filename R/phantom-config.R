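## Regional ground-truth defaults for the simulated longitudinal infarct
## study: a porcine left ventricle imaged at baseline (pre-occlusion), in the
## acute stage (day 6 after a 90-min LCX occlusion) and at two chronic
## follow-ups (weeks 5 and 9). The infarct sits in the inferolateral wall;
## the septum serves as the remote reference zone. Values are the study
## conditions the phantom emulates:
##   - day-6 infarct T2 83 ms vs 61 ms remote / 58 ms healthy (acute edema),
##     normalising towards baseline in the chronic stage;
##   - infarct native T1 in the 1099-1128 ms range across day 6 .. week 9
##     (< 3% drift) vs ~1000 ms healthy myocardium at 1.5 T;
##   - infarct MD raised 17/33/29% and FA lowered 31/38/36% relative to the
##     pre-infarct baseline at day 6 / week 5 / week 9 (healthy MD
##     1.5e-3 mm^2/s, FA 0.45);
##   - infarct ECV raised 125/157/146% over a healthy 0.25 baseline; the
##     post-contrast T1 ground truth is derived from the target ECV via
##     t1PostForECV() so the ECV stage closes exactly.
.bloodT1pre <- 1550
.bloodT1post <- 300
.hctDefault <- 0.33

.regionalTable <- local({
  inf <- data.frame(
    timepoint = rep(c("baseline", "day6", "week5", "week9"), each = 2),
    region = rep(c("remote", "infarct"), 4),
    T1native = c(1000, 1000, 1010, 1099, 1010, 1128, 1010, 1113),
    T2 = c(58, 58, 61, 83, 61, 62, 60, 60),
    MD = c(1.50, 1.50, 1.50, 1.755, 1.50, 1.995, 1.50, 1.935),
    FA = c(0.45, 0.45, 0.45, 0.3105, 0.45, 0.279, 0.45, 0.288),
    ECV = c(0.25, 0.25, 0.26, 0.5625, 0.26, 0.6425, 0.26, 0.615),
    scar = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE)
  )
  ctl <- inf[inf$region == "remote", ]
  ctl <- rbind(ctl, transform(ctl, region = "infarct"))
  ctl$T1native <- 1000; ctl$T2 <- 58; ctl$MD <- 1.5; ctl$FA <- 0.45
  ctl$ECV <- 0.25; ctl$scar <- FALSE
  list(infarct = inf, control = ctl)
})

## Motion/architecture defaults per cohort and timepoint: torsion (deg/mm),
## global strains (%), and the transmural HA gradient (deg/%) realised as a
## symmetric endo/epi helix-angle ramp (haEndo = -haEpi = 50*|gradient|).
.motionTable <- data.frame(
  cohort = rep(c("control", "infarct"), each = 4),
  timepoint = rep(c("baseline", "day6", "week5", "week9"), 2),
  GRS = c(39, 47, 49, 40, 40, 42, 37, 38),
  GCS = c(-16, -18, -18, -17, -15, -14, -15, -14),
  GLS = c(-17, -17, -17, -16, -17, -16, -15, -14),
  torsion = c(0.23, 0.26, 0.31, 0.28, 0.20, 0.23, 0.20, 0.21),
  haGradient = c(-1.02, -1.19, -1.17, -1.16, -1.04, -1.16, -1.26, -1.26)
)

#' Post-contrast T1 implied by a target ECV
#'
#' Inverts the ECV relation
#' \code{ECV = (1 - Hct) * dR1_myo / dR1_blood} for the myocardial
#' post-contrast T1, so that a phantom configured with a target ECV closes
#' exactly through the ECV mapping stage.
#'
#' @param ecv target ECV fraction.
#' @param t1native native myocardial T1 (ms).
#' @param bloodT1pre,bloodT1post blood-pool T1 before/after contrast (ms).
#' @param hematocrit hematocrit fraction.
#' @return Post-contrast myocardial T1 (ms).
#' @examples
#' t1PostForECV(0.25, 1000, 1550, 300, 0.33)
#' @export
t1PostForECV <- function(ecv, t1native, bloodT1pre = .bloodT1pre,
                         bloodT1post = .bloodT1post,
                         hematocrit = .hctDefault) {
  dR1b <- 1 / bloodT1post - 1 / bloodT1pre
  if (dR1b <= 0) stop("blood delta-R1 must be positive")
  1 / (1 / t1native + ecv * dR1b / (1 - hematocrit))
}

#' Construct a phantom configuration
#'
#' Builds a \linkS4class{PhantomConfig}. All arguments have defaults
#' describing the simulated study's acquisition geometry (2 mm in-plane
#' pixels, 8 mm slices, 10 slices apex to base) and, per timepoint and
#' cohort, the regional ground truth of the longitudinal infarct timeline
#' (see \code{\link{defaultPhantomConfig}}).
#'
#' @param nSlices,sliceThickness,sliceGap,pixelSpacing,gridSize geometry;
#'   see \linkS4class{PhantomConfig}.
#' @param endoRadius,epiRadius annulus radii in mm (scalar or per slice).
#' @param rvInsertionAngle anterior RV insertion angle (degrees); zero of
#'   the AHA parcellation.
#' @param infarctSector numeric length-2, start/end angle (degrees) of the
#'   infarcted sector; identical values give an infarct-free phantom.
#' @param infarctSlices integer slice indices carrying the infarct.
#' @param bloodPool logical, include cavity voxels.
#' @param hematocrit blood hematocrit fraction.
#' @param timepoint label: \code{"baseline"}, \code{"day6"}, \code{"week5"}
#'   or \code{"week9"}.
#' @param regional data.frame of per-region values (columns \code{region},
#'   \code{T1native}, \code{T1post}, \code{T2}, \code{MD} in 1e-3 mm^2/s,
#'   \code{FA}, \code{scar}).
#' @param haEndo,haEpi transmural helix-angle endpoints (degrees).
#' @param torsionSlope prescribed torsion (degrees/mm).
#' @param peakContractionFraction cycle fraction of peak contraction.
#' @param strainTargets named numeric, target GRS/GCS/GLS in percent.
#' @param noiseSigma noise sd as a fraction of each acquisition's reference
#'   signal (1/30, i.e. SNR 30, by default).
#' @param seed integer RNG seed.
#' @return A validated \linkS4class{PhantomConfig}.
#' @export
phantomConfig <- function(nSlices = 10L, sliceThickness = 8, sliceGap = 0,
                          pixelSpacing = 2, gridSize = c(64L, 64L),
                          endoRadius = 20, epiRadius = 30,
                          rvInsertionAngle = 0,
                          infarctSector = c(240, 319.2),
                          infarctSlices = 4:8,
                          bloodPool = TRUE, hematocrit = .hctDefault,
                          timepoint = "baseline",
                          regional = NULL,
                          haEndo = 52, haEpi = -52,
                          torsionSlope = 0.2,
                          peakContractionFraction = 0.35,
                          strainTargets = c(GRS = 40, GCS = -15, GLS = -17),
                          noiseSigma = 1 / 30, seed = 1L) {
  if (is.null(regional)) {
    tab <- .regionalTable$infarct
    regional <- tab[tab$timepoint == timepoint, -1L]
    if (!nrow(regional)) stop("unknown timepoint '", timepoint, "'")
  }
  if (!"T1post" %in% names(regional)) {
    if (!"ECV" %in% names(regional))
      stop("regional table needs either T1post or a target ECV column")
    regional$T1post <- t1PostForECV(regional$ECV, regional$T1native,
                                    hematocrit = hematocrit)
  }
  if (!"blood" %in% regional$region)
    regional <- rbind(regional[, c("region", "T1native", "T1post", "T2",
                                   "MD", "FA", "scar")],
                      data.frame(region = "blood",
                                 T1native = .bloodT1pre,
                                 T1post = .bloodT1post,
                                 T2 = 250, MD = 3.0, FA = 0.05,
                                 scar = FALSE))
  new("PhantomConfig",
      nSlices = as.integer(nSlices), sliceThickness = sliceThickness,
      sliceGap = sliceGap, pixelSpacing = pixelSpacing,
      gridSize = as.integer(gridSize),
      endoRadius = endoRadius, epiRadius = epiRadius,
      rvInsertionAngle = rvInsertionAngle,
      infarctSector = infarctSector,
      infarctSlices = as.integer(infarctSlices),
      bloodPool = bloodPool, hematocrit = hematocrit,
      timepoint = timepoint, regional = regional,
      haEndo = haEndo, haEpi = haEpi, torsionSlope = torsionSlope,
      peakContractionFraction = peakContractionFraction,
      strainTargets = strainTargets,
      noiseSigma = noiseSigma, seed = as.integer(seed))
}

#' Default phantom configuration for a study timepoint
#'
#' Returns the \linkS4class{PhantomConfig} encoding the simulated study's
#' conditions at one timepoint for one cohort: regional relaxometry,
#' diffusion and ECV ground truth following the acute-to-chronic infarct
#' timeline, torsion and strain targets, and the symmetric transmural
#' helix-angle ramp whose slope equals the configured transmural HA
#' gradient. Control-cohort phantoms keep healthy values throughout and
#' carry no scar.
#'
#' @param timepoint \code{"baseline"}, \code{"day6"}, \code{"week5"} or
#'   \code{"week9"}.
#' @param cohort \code{"infarct"} or \code{"control"}.
#' @param seed integer RNG seed.
#' @param ... further arguments passed to \code{\link{phantomConfig}}
#'   (e.g. \code{gridSize}, \code{noiseSigma}).
#' @return A \linkS4class{PhantomConfig}.
#' @examples
#' cfg <- defaultPhantomConfig("day6")
#' cfg
#' @export
defaultPhantomConfig <- function(timepoint = "baseline",
                                 cohort = c("infarct", "control"),
                                 seed = 1L, ...) {
  cohort <- match.arg(cohort)
  tab <- .regionalTable[[cohort]]
  regional <- tab[tab$timepoint == timepoint, -1L]
  if (!nrow(regional)) stop("unknown timepoint '", timepoint, "'")
  mo <- .motionTable[.motionTable$cohort == cohort &
                     .motionTable$timepoint == timepoint, ]
  args <- list(timepoint = timepoint, regional = regional,
               haEndo = 50 * abs(mo$haGradient),
               haEpi = -50 * abs(mo$haGradient),
               torsionSlope = mo$torsion,
               strainTargets = c(GRS = mo$GRS, GCS = mo$GCS, GLS = mo$GLS),
               seed = seed)
  if (cohort == "control") {
    args$infarctSector <- c(0, 0)
    args$infarctSlices <- integer()
  }
  do.call(phantomConfig, utils::modifyList(args, list(...)))
}

#' Default study configuration
#'
#' Study-level configuration for \code{\link{runStudy}}: cohort sizes
#' (5 infarct, 4 control), the four timepoints, per-subject seed offsets and
#' shared phantom overrides.
#'
#' @param nInfarct,nControl cohort sizes.
#' @param timepoints timepoint labels to simulate.
#' @param seed base seed; subject s at timepoint t uses
#'   \code{seed + 97 * subjectIndex + t}.
#' @param modalities character subset of
#'   \code{c("t2", "t1", "dwi", "lge", "motion")} to simulate and fit.
#' @param ... phantom overrides applied to every subject (passed to
#'   \code{\link{defaultPhantomConfig}}).
#' @return A list with class \code{"StudyConfig"}.
#' @export
defaultStudyConfig <- function(nInfarct = 5L, nControl = 4L,
                               timepoints = c("baseline", "day6",
                                              "week5", "week9"),
                               seed = 1L,
                               modalities = c("t2", "t1", "dwi", "lge",
                                              "motion"),
                               ...) {
  stopifnot(all(timepoints %in% c("baseline", "day6", "week5", "week9")))
  structure(list(nInfarct = as.integer(nInfarct),
                 nControl = as.integer(nControl),
                 timepoints = timepoints, seed = as.integer(seed),
                 modalities = match.arg(modalities, several.ok = TRUE),
                 overrides = list(...)),
            class = "StudyConfig")
}
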