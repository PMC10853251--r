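## Class-conditional cohort feature model: published control/CHF marginals
## with a single latent severity factor, plus group-difference statistics.

.TABLE_CONTROL_MEAN <- c(hi_interval_ms = 65, im_interval_ms = 310,
                         mn_interval_ms = 69, hi_amp_v = 0.900,
                         ij_amp_v = 2.715, mn_amp_v = 1.160,
                         hi_slope_vps = -18.450, ij_slope_vps = 35.707,
                         mn_slope_vps = 13.161)
.TABLE_CONTROL_SD <- c(hi_interval_ms = 12, im_interval_ms = 33,
                       mn_interval_ms = 12, hi_amp_v = 0.219,
                       ij_amp_v = 0.716, mn_amp_v = 0.480,
                       hi_slope_vps = 6.530, ij_slope_vps = 9.026,
                       mn_slope_vps = 5.110)
.TABLE_CHF_MEAN <- c(hi_interval_ms = 102, im_interval_ms = 260,
                     mn_interval_ms = 93, hi_amp_v = 1.286,
                     ij_amp_v = 2.163, mn_amp_v = 1.405,
                     hi_slope_vps = -15.018, ij_slope_vps = 27.916,
                     mn_slope_vps = 15.733)
.TABLE_CHF_SD <- c(hi_interval_ms = 32, im_interval_ms = 37,
                   mn_interval_ms = 25, hi_amp_v = 0.497,
                   ij_amp_v = 0.803, mn_amp_v = 0.695,
                   hi_slope_vps = 9.364, ij_slope_vps = 11.586,
                   mn_slope_vps = 6.969)

#' Cohort distribution parameters
#'
#' Builds the class-conditional feature model: per-class means and standard
#' deviations of the nine BCG features (defaults are the published control
#' and CHF marginals), a shared latent severity factor with loading
#' \code{latentLoading} (fraction of each feature's variance), and
#' physiological truncation bounds.
#'
#' @param latentLoading latent-factor variance fraction in [0, 0.9].
#' @param repeatIcc intraclass correlation of repeated samples of one
#'   subject; the default 0.85 reflects the high test-retest stability of
#'   BCG cardiac time intervals (median absolute errors of a few ms against
#'   reference methods).
#' @param rowsPerSubject average repeated samples per subject; the default
#'   reproduces the source study's 541 analyses of 162 subjects.
#' @param means,sds optional 2 x 9 matrices (rows control/chf) overriding
#'   the defaults.
#' @param bounds optional 2 x 9 matrix (rows lower/upper) of truncation
#'   bounds.
#' @return a \linkS4class{CohortParams}.
#' @export
cohortParams <- function(latentLoading = 0.5, repeatIcc = 0.85,
                         rowsPerSubject = 541 / 162, means = NULL,
                         sds = NULL, bounds = NULL) {
  if (is.null(means))
    means <- rbind(control = .TABLE_CONTROL_MEAN, chf = .TABLE_CHF_MEAN)
  if (is.null(sds))
    sds <- rbind(control = .TABLE_CONTROL_SD, chf = .TABLE_CHF_SD)
  if (is.null(bounds)) {
    bounds <- rbind(
      lower = c(20, 120, 20, 0.05, 0.20, 0.05, -60, 2, 1),
      upper = c(200, 450, 200, 6, 8, 6, -1, 90, 45))
    colnames(bounds) <- FEATURE_NAMES
  }
  new("CohortParams", means = means, sds = sds, bounds = bounds,
      latentLoading = latentLoading, repeatIcc = repeatIcc,
      rowsPerSubject = rowsPerSubject,
      hrMean = c(control = 73.02, chf = 79.52),
      hrSd = c(control = 12.19, chf = 16.61),
      hrBounds = c(40, 140))
}

## one subject's nine features under the latent-factor model:
## f_i = mean_i + sd_i (sqrt(lambda) z + sqrt(1 - lambda) eps_i)
.draw_subject <- function(params, classLabel, maxTries = 1000) {
  mu <- params@means[classLabel, ]
  sd <- params@sds[classLabel, ]
  lam <- params@latentLoading
  lo <- params@bounds["lower", ]
  hi <- params@bounds["upper", ]
  for (i in seq_len(maxTries)) {
    z <- stats::rnorm(1)
    eps <- stats::rnorm(9)
    f <- mu + sd * (sqrt(lam) * z + sqrt(1 - lam) * eps)
    if (all(f >= lo & f <= hi)) return(f)
  }
  stop("sampling error: truncation bounds infeasible after ", maxTries,
       " rejections")
}

#' Sample a labeled repeated-measures feature cohort
#'
#' Draws \code{nControl} control and \code{nChf} CHF rows as repeated
#' samples of underlying subjects (about \code{rowsPerSubject} rows each),
#' mirroring a study design in which each participant contributes several
#' cardiac-cycle analyses. Each subject carries a profile
#' \code{sqrt(icc) (sqrt(lambda) z + sqrt(1 - lambda) e)} and each row adds
#' an independent within-subject state with the complementary variance
#' share, so large-sample marginal means and sds match the configured class
#' marginals, any two features within a class correlate at about
#' \code{latentLoading}, and repeated rows of one subject correlate at about
#' \code{repeatIcc}. Rows violating the truncation bounds are redrawn.
#'
#' @param params a \linkS4class{CohortParams}.
#' @param nControl,nChf rows per class (>= 2 each).
#' @param seed integer RNG seed.
#' @return data.frame with columns subject_id, class (factor control/CHF)
#'   and the nine features.
#' @export
#' @examples
#' tab <- sampleFeatures(cohortParams(), 20, 12, seed = 1)
#' aggregate(hi_interval_ms ~ class, tab, mean)
sampleFeatures <- function(params, nControl, nChf, seed = 1) {
  validObject(params)
  if (nControl < 2 || nChf < 2)
    stop("sampling error: need at least 2 rows per class")
  set.seed(as.integer(seed))
  lam <- params@latentLoading
  icc <- params@repeatIcc
  lo <- params@bounds["lower", ]
  hi <- params@bounds["upper", ]
  draw_class <- function(classLabel, n) {
    mu <- params@means[classLabel, ]
    sd <- params@sds[classLabel, ]
    nsub <- max(2L, as.integer(round(n / params@rowsPerSubject)))
    rows_per <- rep(n %/% nsub, nsub)
    extra <- n - sum(rows_per)
    if (extra > 0) rows_per[seq_len(extra)] <- rows_per[seq_len(extra)] + 1L
    rows <- vector("list", n)
    sid <- character(n)
    r_i <- 0L
    for (s in seq_len(nsub)) {
      for (try_subj in seq_len(100)) {
        z <- stats::rnorm(1)
        e <- stats::rnorm(9)
        prof <- sqrt(icc) * (sqrt(lam) * z + sqrt(1 - lam) * e)
        subj_rows <- vector("list", rows_per[s])
        ok <- TRUE
        for (r in seq_len(rows_per[s])) {
          got <- FALSE
          for (try_row in seq_len(100)) {
            w <- stats::rnorm(1)
            eta <- stats::rnorm(9)
            f <- mu + sd * (prof + sqrt(1 - icc) *
                              (sqrt(lam) * w + sqrt(1 - lam) * eta))
            if (all(f >= lo & f <= hi)) {
              subj_rows[[r]] <- f
              got <- TRUE
              break
            }
          }
          if (!got) { ok <- FALSE; break }
        }
        if (ok) break
        if (try_subj == 100)
          stop("sampling error: truncation bounds infeasible")
      }
      for (r in seq_len(rows_per[s])) {
        r_i <- r_i + 1L
        rows[[r_i]] <- subj_rows[[r]]
        sid[r_i] <- sprintf("%s_%03d", classLabel, s)
      }
    }
    out <- as.data.frame(do.call(rbind, rows))
    names(out) <- FEATURE_NAMES
    out$subject_id <- sid
    out
  }
  ctrl <- draw_class("control", nControl)
  chf <- draw_class("chf", nChf)
  out <- rbind(ctrl, chf)
  out <- cbind(subject_id = out$subject_id,
               class = factor(rep(c("control", "CHF"), c(nControl, nChf)),
                              levels = c("control", "CHF")),
               out[FEATURE_NAMES])
  rownames(out) <- NULL
  out
}

#' Per-feature group comparison between control and CHF
#'
#' Welch's two-sample t-test per feature (the cohorts are independent), with
#' class means, sds, the t statistic, the two-sided p value and the
#' direction of change in CHF. Repeated samples of one subject are not
#' independent observations, so when a \code{subject_id} column is present
#' rows are first averaged per subject (set \code{bySubject = FALSE} to
#' compare raw rows).
#'
#' @param table a labeled feature table from \code{\link{sampleFeatures}}
#'   (or the pipeline), with a two-level \code{class} column.
#' @param bySubject average repeated rows per subject before testing.
#' @return data.frame with one row per feature.
#' @export
groupCompare <- function(table, bySubject = TRUE) {
  if (!"class" %in% names(table)) stop("comparison error: no class column")
  feats <- intersect(FEATURE_NAMES, names(table))
  if (!length(feats)) stop("comparison error: no feature columns")
  if (bySubject && !is.null(table$subject_id) &&
      anyDuplicated(table$subject_id)) {
    agg <- stats::aggregate(table[feats],
                            by = list(subject_id = table$subject_id,
                                      class = table$class), mean)
    table <- agg
  }
  cls <- droplevels(factor(table$class))
  if (nlevels(cls) != 2)
    stop("comparison error: need exactly two classes")
  ref <- levels(cls)[1]
  alt <- levels(cls)[2]
  rows <- lapply(feats, function(f) {
    x <- table[[f]][cls == ref]
    y <- table[[f]][cls == alt]
    tt <- stats::t.test(y, x)  # Welch by default
    data.frame(feature = f,
               mean_control = mean(x), sd_control = stats::sd(x),
               mean_chf = mean(y), sd_chf = stats::sd(y),
               t_statistic = unname(tt$statistic),
               p_value = tt$p.value,
               direction = if (mean(y) > mean(x)) "up" else "down",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
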