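# Method-agreement statistics: per-parameter paired comparison of the two
# modalities across participants - normality, paired t-test,
# convergent-validity correlation and Bland-Altman limits of agreement.
#
# Conventions: differences are IMU minus kinematic; the LoA multiplier
# defaults to 1.96 (the value matching reported half-widths in validation
# practice, even where plots are captioned "doubled SD"); the SD of the
# differences uses the n-1 denominator; no multiple-testing correction is
# applied (single alpha = 0.05).

#' Shapiro-Wilk normality test
#'
#' @param values Numeric vector, 3 to 5000 observations.
#' @return List with the `W` statistic and `p` value.
#' @export
normality_test <- function(values) {
  n <- sum(is.finite(values))
  if (n < 3 || n > 5000) {
    stop("normality test requires 3 to 5000 observations", call. = FALSE)
  }
  ht <- shapiro.test(values[is.finite(values)])
  list(W = unname(ht$statistic), p = ht$p.value)
}

#' Two-sided paired t-test
#'
#' Zero-variance differences are handled explicitly: identical vectors give
#' `t = 0, p = 1`; a constant non-zero offset is reported with `p = 0` and
#' an `exact_offset` flag.
#'
#' @param values_a,values_b Paired numeric vectors of equal length >= 2.
#' @return List with `t`, `p`, `mean_diff` (a minus b) and `exact_offset`.
#' @export
paired_t <- function(values_a, values_b) {
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 2)
  d <- values_a - values_b
  if (sd(d) == 0) {
    if (all(d == 0)) {
      return(list(t = 0, p = 1, mean_diff = 0, exact_offset = FALSE))
    }
    return(list(t = sign(mean(d)) * Inf, p = 0, mean_diff = mean(d),
                exact_offset = TRUE))
  }
  ht <- t.test(values_a, values_b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, mean_diff = mean(d),
       exact_offset = FALSE)
}

#' Convergent-validity correlation
#'
#' Pearson product-moment correlation when both margins are normal
#' (Shapiro-Wilk at `alpha`), Spearman rank correlation otherwise; the
#' choice is recorded.
#'
#' @param values_a,values_b Paired numeric vectors of equal length >= 3.
#' @param normal Optional logical overriding the normality gate.
#' @param alpha Significance level of the normality gate.
#' @return List with `method` (`"pearson"` or `"spearman"`), `r` and `p`.
#' @export
correlate <- function(values_a, values_b, normal = NULL, alpha = 0.05) {
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 3)
  if (is.null(normal)) {
    normal <- normality_test(values_a)$p > alpha &&
      normality_test(values_b)$p > alpha
  }
  method <- if (isTRUE(normal)) "pearson" else "spearman"
  ht <- suppressWarnings(
    cor.test(values_a, values_b, method = method, exact = FALSE)
  )
  list(method = method, r = unname(ht$estimate), p = ht$p.value)
}

#' Bland-Altman agreement analysis
#'
#' Differences are `a - b`; limits of agreement are
#' `mean_diff +/- multiplier * sd_diff` with the sample (n-1) SD. Pairs
#' strictly outside the limits are counted.
#'
#' @param values_a,values_b Paired numeric vectors of equal length >= 2.
#' @param multiplier LoA multiplier (default 1.96).
#' @return Object of class `bland_altman`: `n`, `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, `loa_multiplier`, `n_outside_loa`,
#'   `pct_outside_loa`, and the per-pair `means` and `diffs`.
#' @export
bland_altman <- function(values_a, values_b, multiplier = 1.96) {
  stopifnot(length(values_a) == length(values_b))
  n <- length(values_a)
  if (n < 2) stop("Bland-Altman needs at least 2 pairs", call. = FALSE)
  d <- values_a - values_b
  m <- mean(d); s <- sd(d)
  lo <- m - multiplier * s
  hi <- m + multiplier * s
  outside <- sum(d < lo | d > hi)
  structure(
    list(n = n, mean_diff = m, sd_diff = s, loa_low = lo, loa_high = hi,
         loa_multiplier = multiplier, n_outside_loa = outside,
         pct_outside_loa = 100 * outside / n,
         means = (values_a + values_b) / 2, diffs = d),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (n = %d): mean diff %.4g +/- %.4g, LoA [%.4g, %.4g], %d (%.1f%%) outside\n",
    x$n, x$mean_diff, x$sd_diff, x$loa_low, x$loa_high, x$n_outside_loa,
    x$pct_outside_loa))
  invisible(x)
}

#' Full per-parameter agreement report
#'
#' For each gait parameter present in both modalities, computes normality
#' per method, the paired t-test, the normality-gated correlation and the
#' Bland-Altman statistics over participants, with differences taken as
#' IMU minus kinematic. Participants missing either modality for a
#' parameter are dropped (count logged).
#'
#' @param summaries Data frame of summary rows: columns `participant`,
#'   `source` (`"KINEMATIC"`/`"IMU"`) and one column per parameter.
#' @param parameters Parameter columns to analyse; defaults to all numeric
#'   columns except bookkeeping ones.
#' @param multiplier LoA multiplier.
#' @param alpha Significance level for the normality gate.
#' @return Object of class `agreement_report`: `report` (one row per
#'   parameter), `bland_altman` and `correlation` per-parameter scatter
#'   data, `n_dropped` per parameter.
#' @export
full_report <- function(summaries, parameters = NULL, multiplier = 1.96,
                        alpha = 0.05) {
  stopifnot(all(c("participant", "source") %in% names(summaries)))
  if (is.null(parameters)) {
    num <- names(summaries)[vapply(summaries, is.numeric, logical(1))]
    parameters <- setdiff(num, c("n_strides", "window_s"))
  }
  rows <- NULL; ba_data <- list(); cor_data <- list()
  n_dropped <- integer(0)
  for (par in parameters) {
    a <- summaries[summaries$source == "IMU", c("participant", par)]
    b <- summaries[summaries$source == "KINEMATIC", c("participant", par)]
    merged <- merge(a, b, by = "participant", suffixes = c("_imu", "_kin"))
    ok <- stats::complete.cases(merged)
    merged <- merged[ok, , drop = FALSE]
    n <- nrow(merged)
    if (n < 2) next # parameter not measurable by both methods
    n_dropped[par] <- length(unique(summaries$participant)) - n
    imu <- merged[[paste0(par, "_imu")]]
    kin <- merged[[paste0(par, "_kin")]]
    tt <- paired_t(imu, kin)
    ba <- bland_altman(imu, kin, multiplier)
    if (n >= 3) {
      norm_imu <- normality_test(imu)$p
      norm_kin <- normality_test(kin)$p
      cr <- correlate(imu, kin, normal = norm_imu > alpha &&
                        norm_kin > alpha)
    } else {
      norm_imu <- NA_real_; norm_kin <- NA_real_
      cr <- list(method = NA_character_, r = NA_real_, p = NA_real_)
    }
    rows <- rbind(rows, data.frame(
      parameter = par, n = n,
      normality_p_imu = norm_imu, normality_p_kin = norm_kin,
      t = tt$t, t_p = tt$p,
      cor_method = cr$method, cor_r = cr$r, cor_p = cr$p,
      mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
      loa_low = ba$loa_low, loa_high = ba$loa_high,
      loa_multiplier = multiplier,
      n_outside_loa = ba$n_outside_loa,
      pct_outside_loa = ba$pct_outside_loa
    ))
    ba_data[[par]] <- data.frame(participant = merged$participant,
                                 mean = ba$means, diff = ba$diffs)
    cor_data[[par]] <- data.frame(participant = merged$participant,
                                  kinematic = kin, imu = imu)
  }
  if (is.null(rows)) {
    stop("need at least 2 participants with both modalities", call. = FALSE)
  }
  dropped <- n_dropped[n_dropped > 0]
  if (length(dropped)) {
    message("full_report: dropped incomplete participants: ",
            paste(sprintf("%s=%d", names(dropped), dropped), collapse = ", "))
  }
  structure(list(report = rows, bland_altman = ba_data,
                 correlation = cor_data, n_dropped = n_dropped),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Agreement report (IMU - kinematic):\n")
  print(x$report, digits = 4, row.names = FALSE)
  invisible(x)
}
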