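#' Mean and SD of paired differences
#'
#' @param a,b Equal-length numeric vectors (two raters' measurements of the
#'   same subjects, degrees).
#' @return List with \code{mean} and \code{sd} (sample SD, n - 1) of
#'   \code{a - b}.
#' @export
mean_difference <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (length(a) < 2L) stop("need at least 2 paired measurements")
  d <- a - b
  list(mean = mean(d), sd = stats::sd(d))
}

#' Bland-Altman limits of agreement
#'
#' Computes the per-pair (mean, difference) coordinates, the mean difference,
#' the limits of agreement mean +/- coverage * SD, and the number of pairs
#' falling outside them.
#'
#' @param a,b Equal-length numeric vectors.
#' @param coverage Half-width multiplier for the limits (default 1.96, the
#'   95\% limits).
#' @return List with \code{mean_diff}, \code{sd_diff}, \code{loa_low},
#'   \code{loa_high}, \code{n_outside}, and a data frame \code{points} with
#'   columns \code{mean} and \code{diff} for plotting.
#' @export
bland_altman <- function(a, b, coverage = 1.96) {
  md <- mean_difference(a, b)
  d <- a - b
  lo <- md$mean - coverage * md$sd
  hi <- md$mean + coverage * md$sd
  list(mean_diff = md$mean, sd_diff = md$sd,
       loa_low = lo, loa_high = hi,
       n_outside = sum(d < lo | d > hi),
       points = data.frame(mean = (a + b) / 2, diff = d))
}

#' Two-way ANOVA decomposition of a measurement matrix
#'
#' The standard two-way decomposition without replication (subjects = rows,
#' raters = columns): total sum of squares split into row, column and
#' residual components, reported as mean squares. This is the decomposition
#' underlying the absolute-agreement intraclass correlation.
#'
#' @param values Complete numeric S x R matrix, S >= 2 subjects, R >= 2
#'   raters.
#' @return List with \code{MSR} (rows), \code{MSC} (columns), \code{MSE}
#'   (error), \code{n} (subjects), \code{k} (raters) and the sums of squares
#'   \code{SSR}, \code{SSC}, \code{SSE}, \code{SST}.
#' @export
two_way_anova <- function(values) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("measurement matrix has missing cells")
  n <- nrow(values); k <- ncol(values)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 raters")
  gm <- mean(values)
  ssr <- k * sum((rowMeans(values) - gm)^2)
  ssc <- n * sum((colMeans(values) - gm)^2)
  sst <- sum((values - gm)^2)
  sse <- sst - ssr - ssc
  list(MSR = ssr / (n - 1), MSC = ssc / (k - 1),
       MSE = sse / ((n - 1) * (k - 1)),
       n = n, k = k, SSR = ssr, SSC = ssc, SSE = sse, SST = sst)
}

#' Two-way absolute-agreement intraclass correlation
#'
#' ICC from the two-way decomposition, in the absolute-agreement family that
#' penalizes systematic offsets between raters. The single-measures form is
#'
#'   (MSR - MSE) / (MSR + (k - 1) MSE + k (MSC - MSE) / n)
#'
#' and the average-measures form is
#'
#'   (MSR - MSE) / (MSR + (MSC - MSE) / n).
#'
#' The default is \code{"single"}: applied to per-subject mean measurements
#' it reproduces the published comparison-study coefficients to three
#' decimals, whereas the average-measures form does not; both forms are
#' exposed.
#'
#' @param values Numeric S x R matrix (typically R = 2 raters).
#' @param form \code{"single"} (default) or \code{"average"}.
#' @return ICC scalar in [-1, 1].
#' @export
icc_absolute <- function(values, form = c("single", "average")) {
  form <- match.arg(form)
  a <- two_way_anova(values)
  if (a$MSR == 0 && a$MSE == 0)
    stop("degenerate matrix: no subject variance, ICC undefined")
  with(a, if (form == "single")
    (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  else
    (MSR - MSE) / (MSR + (MSC - MSE) / n))
}

#' F-based confidence interval for the absolute-agreement ICC
#'
#' McGraw-Wong construction for the two-way absolute-agreement family, using
#' a Satterthwaite-approximated denominator degrees of freedom. The interval
#' always contains the point estimate; for a perfectly agreeing matrix it
#' degenerates to [1, 1].
#'
#' @inheritParams icc_absolute
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector \code{c(low=, high=)}.
#' @export
icc_confidence_interval <- function(values, form = c("single", "average"),
                                    level = 0.95) {
  form <- match.arg(form)
  a <- two_way_anova(values)
  est <- icc_absolute(values, form = "single")
  n <- a$n; k <- a$k
  alpha <- 1 - level
  if (a$MSE == 0 && a$MSC == a$MSE) {
    ci <- c(low = 1, high = 1)
    return(ci)
  }
  Fj <- a$MSC / a$MSE
  vn <- (k - 1) * (n - 1) *
    (k * est * Fj + n * (1 + (k - 1) * est) - k * est)^2
  vd <- (n - 1) * k^2 * est^2 * Fj^2 +
    (n * (1 + (k - 1) * est) - k * est)^2
  v <- vn / vd
  FL <- stats::qf(1 - alpha / 2, n - 1, v)
  FU <- stats::qf(1 - alpha / 2, v, n - 1)
  low1 <- n * (a$MSR - FL * a$MSE) /
    (FL * (k * a$MSC + (k * n - k - n) * a$MSE) + n * a$MSR)
  high1 <- n * (FU * a$MSR - a$MSE) /
    (k * a$MSC + (k * n - k - n) * a$MSE + n * FU * a$MSR)
  ci1 <- c(low = max(-1, low1), high = min(1, high1))
  if (form == "single") return(ci1)
  # average-measures bounds via the Spearman-Brown step-up of the single form
  stepup <- function(r) r * k / (1 + (k - 1) * r)
  c(low = max(-1, stepup(ci1[["low"]])), high = min(1, stepup(ci1[["high"]])))
}

#' Full pairwise agreement report for a measurement matrix
#'
#' For each requested rater pair: mean difference, SD, limits of agreement,
#' outside count, and single/average absolute-agreement ICC with confidence
#' interval.
#'
#' @param values Numeric S x R matrix with column names.
#' @param pairs List of length-2 character (or index) vectors naming column
#'   pairs; default all unordered pairs.
#' @param coverage Bland-Altman coverage multiplier.
#' @param level Confidence level for the ICC interval.
#' @return Data frame with one row per pair: \code{pair}, \code{mean_diff},
#'   \code{sd_diff}, \code{loa_low}, \code{loa_high}, \code{n_outside},
#'   \code{icc_single}, \code{icc_average}, \code{ci_low}, \code{ci_high}.
#' @export
agreement_report <- function(values, pairs = NULL, coverage = 1.96,
                             level = 0.95) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("R", seq_len(ncol(values)))
  if (is.null(pairs)) {
    cmb <- utils::combn(colnames(values), 2L, simplify = FALSE)
    pairs <- cmb
  }
  rows <- lapply(pairs, function(pr) {
    sub <- values[, pr, drop = FALSE]
    ba <- bland_altman(sub[, 1], sub[, 2], coverage = coverage)
    ci <- icc_confidence_interval(sub, form = "single", level = level)
    data.frame(pair = paste(colnames(sub), collapse = "-"),
               mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
               loa_low = ba$loa_low, loa_high = ba$loa_high,
               n_outside = ba$n_outside,
               icc_single = icc_absolute(sub, "single"),
               icc_average = icc_absolute(sub, "average"),
               ci_low = ci[["low"]], ci_high = ci[["high"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
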