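#' Regional summaries
#'
#' Averages parameter maps across regions of interest, producing the long
#' region table that feeds the comparison statistics: one row per
#' (subject, timepoint, region, parameter) with the ROI mean, SD and voxel
#' count. Non-finite voxels (fit failures) are excluded; an empty ROI is
#' omitted with a warning.
#'
#' @param maps named list of numeric arrays (one per parameter).
#' @param roi integer label array (1 remote, 2 infarct) or a named list of
#'   logical masks.
#' @param subject,group,timepoint row metadata (group is
#'   \code{"control"} or \code{"infarct"}).
#' @param units optional named character vector of units per parameter.
#' @return data.frame with columns \code{subject}, \code{group},
#'   \code{timepoint}, \code{region}, \code{parameter}, \code{value},
#'   \code{sd}, \code{n}, \code{units}.
#' @export
summarizeRegions <- function(maps, roi, subject, group = "infarct",
                             timepoint = "baseline", units = NULL) {
  if (!is.list(roi))
    roi <- list(remote = roi == 1L, infarct = roi == 2L)
  rows <- list()
  for (pname in names(maps)) {
    for (rname in names(roi)) {
      v <- maps[[pname]][roi[[rname]]]
      v <- v[is.finite(v)]
      if (!length(v)) {
        warning("empty ROI '", rname, "' for parameter '", pname,
                "'; row omitted")
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subject, group = group, timepoint = timepoint,
        region = rname, parameter = pname, value = mean(v),
        sd = if (length(v) > 1L) sd(v) else 0, n = length(v),
        units = if (!is.null(units) && pname %in% names(units))
          units[[pname]] else NA_character_)
    }
  }
  do.call(rbind, rows)
}

#' Relative parameter change
#'
#' Per-subject relative change of the infarct-region value against a
#' reference, \code{(x_infarct - x_ref) / x_ref}, reported as group
#' mean +/- SD in percent. Two conventions are supported: the reference is
#' the same subject's remote region at the same timepoint
#' (\code{infarct_vs_remote}) or the same subject's infarct region at
#' baseline (\code{infarct_vs_baseline}). Subjects with a zero reference
#' are excluded with a warning; the paired t statistic compares the two
#' operands within subjects.
#'
#' @param table region table from \code{\link{summarizeRegions}}.
#' @param parameter parameter name to contrast.
#' @param timepoint timepoint of the infarct-region values.
#' @param mode \code{"infarct_vs_remote"} or \code{"infarct_vs_baseline"}.
#' @param baselineLabel label of the baseline timepoint.
#' @return List of class \code{"ContrastResult"}: \code{perSubject}
#'   (percent), \code{mean}, \code{sd} (percent), \code{n},
#'   \code{statistic}, \code{p}, \code{testType}.
#' @export
relativeChange <- function(table, parameter, timepoint,
                           mode = c("infarct_vs_remote",
                                    "infarct_vs_baseline"),
                           baselineLabel = "baseline") {
  mode <- match.arg(mode)
  tb <- table[table$parameter == parameter & table$group == "infarct", ]
  x <- tb[tb$timepoint == timepoint & tb$region == "infarct", ]
  ref <- if (mode == "infarct_vs_remote")
    tb[tb$timepoint == timepoint & tb$region == "remote", ]
  else
    tb[tb$timepoint == baselineLabel & tb$region == "infarct", ]
  m <- merge(x[, c("subject", "value")], ref[, c("subject", "value")],
             by = "subject", suffixes = c(".x", ".ref"))
  if (!nrow(m)) stop("no paired subjects for parameter '", parameter, "'")
  zero <- m$value.ref == 0
  if (any(zero)) {
    warning(sum(zero), " subject(s) excluded: zero reference value")
    m <- m[!zero, ]
  }
  rel <- 100 * (m$value.x - m$value.ref) / m$value.ref
  ct <- if (nrow(m) >= 2L)
    compareGroups(m$value.x, m$value.ref, paired = TRUE)
  else list(statistic = NA_real_, p = NA_real_)
  structure(list(perSubject = stats::setNames(rel, m$subject),
                 mean = mean(rel),
                 sd = if (length(rel) > 1L) sd(rel) else 0,
                 n = length(rel), statistic = ct$statistic, p = ct$p,
                 testType = "paired", mode = mode,
                 parameter = parameter, timepoint = timepoint),
            class = "ContrastResult")
}

#' @export
print.ContrastResult <- function(x, ...) {
  cat("ContrastResult [", x$parameter, ", ", x$timepoint, ", ", x$mode,
      "]: ", signif(x$mean, 4), " +/- ", signif(x$sd, 3), "% (n = ", x$n,
      "), paired t = ", signif(x$statistic, 4), ", p = ",
      signif(x$p, 3), "\n", sep = "")
  invisible(x)
}

#' Control-vs-remote bias distribution
#'
#' Evaluates potential bias of the remote zone in infarcted subjects
#' against healthy controls: for every (control i, infarct j) pair the
#' normalized difference
#' \code{d_ij = (remote_j - control_i) / ((remote_j + control_i)/2)} is
#' computed over all possible pairs.
#'
#' @param table region table from \code{\link{summarizeRegions}}; control
#'   subjects contribute their \code{remote} rows.
#' @param parameter parameter name.
#' @param timepoint timepoint to evaluate.
#' @return List with all pairwise \code{values}, their \code{mean} and
#'   \code{sd}, and \code{nPairs}.
#' @export
controlRemoteBias <- function(table, parameter, timepoint) {
  tb <- table[table$parameter == parameter &
                table$timepoint == timepoint &
                table$region == "remote", ]
  ctl <- tb$value[tb$group == "control"]
  rem <- tb$value[tb$group == "infarct"]
  if (!length(ctl) || !length(rem))
    stop("need at least one subject per group")
  pairs <- expand.grid(control = ctl, remote = rem)
  den <- (pairs$remote + pairs$control) / 2
  keep <- den != 0
  if (any(!keep)) warning(sum(!keep), " pair(s) excluded: zero denominator")
  d <- (pairs$remote[keep] - pairs$control[keep]) / den[keep]
  list(values = d, mean = mean(d),
       sd = if (length(d) > 1L) sd(d) else 0, nPairs = length(d))
}

#' Two-tailed Student's t-test
#'
#' Classical Student's t-test, paired (within-subject differences) or
#' unpaired with pooled variance. Degenerate inputs follow fixed
#' conventions: identical samples give t = 0, p = 1; zero-variance paired
#' differences with a nonzero mean give p = 0 with a
#' \code{belowMachine} flag.
#'
#' @param a,b numeric samples (equal length with correspondence when
#'   \code{paired}).
#' @param paired logical.
#' @return List with \code{statistic}, \code{p}, \code{df},
#'   \code{testType}, \code{belowMachine}.
#' @export
compareGroups <- function(a, b, paired = FALSE) {
  if (length(a) < 2L || length(b) < 2L) stop("need n >= 2 per group")
  if (paired && length(a) != length(b))
    stop("paired test requires equal sample sizes")
  type <- if (paired) "paired" else "unpaired"
  scale <- mean(abs(c(a, b))) + .Machine$double.eps
  sdv <- if (paired) sd(a - b) else sd(c(a - mean(a), b - mean(b)))
  degenerate <- sdv <= 1e-12 * scale
  if (degenerate) {
    delta <- mean(a) - mean(b)
    if (delta == 0)
      return(list(statistic = 0, p = 1, df = NA_real_, testType = type,
                  belowMachine = FALSE))
    return(list(statistic = sign(delta) * Inf, p = 0, df = NA_real_,
                testType = type, belowMachine = TRUE))
  }
  tt <- t.test(a, b, paired = paired, var.equal = TRUE)
  list(statistic = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), testType = type, belowMachine = FALSE)
}

#' Pearson correlation with regression line and confidence band
#'
#' Pearson r with the two-tailed p-value from
#' \code{t = r sqrt((n-2)/(1-r^2))}, plus the OLS regression line and its
#' pointwise 95 percent confidence band.
#'
#' @param x,y numeric vectors (n >= 3, finite, non-constant).
#' @param level confidence level for the band.
#' @return List with \code{r}, \code{p}, \code{n}, \code{slope},
#'   \code{intercept} and \code{band} (data.frame x, fit, lwr, upr at the
#'   sorted x values).
#' @examples
#' set.seed(1)
#' x <- rnorm(14); y <- 0.6 * x + rnorm(14, sd = 0.8)
#' correlatePairs(x, y)$r
#' @export
correlatePairs <- function(x, y, level = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 finite pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in x or y")
  ct <- cor.test(x, y, method = "pearson")
  fit <- lm(y ~ x)
  xs <- sort(x)
  band <- cbind(x = xs,
                as.data.frame(predict(fit, newdata = data.frame(x = xs),
                                      interval = "confidence",
                                      level = level)))
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       band = band)
}
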