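#' Two-way consistency ICC for the mean of k repeated measurements
#'
#' Intraclass correlation of McGraw-Wong type ICC(C,k) (two-way model
#' without interaction, consistency definition, average of k measurements):
#' `ICC = (MS_rows - MS_error) / MS_rows` from the subjects x repeats ANOVA.
#' The consistency formula is identical under two-way random and mixed
#' models, so the random/mixed distinction is immaterial here. The
#' confidence interval comes from the F distribution of
#' `MS_rows / MS_error`.
#'
#' @param table numeric matrix, `n` subjects x `k` repeats, no missing
#'   cells, `n >= 2`, `k >= 2`.
#' @param conf confidence level (default 0.95).
#' @return list with `icc`, `lo`, `hi`, `ms_rows`, `ms_error`, `n`, `k`,
#'   and `degenerate` (`TRUE` when the error mean square is zero and the
#'   interval collapses).
#' @export
icc_consistency <- function(table, conf = 0.95) {
  table <- as.matrix(table)
  n <- nrow(table); k <- ncol(table)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 repeats")
  if (any(!is.finite(table))) stop("table contains missing or non-finite cells")
  grand <- mean(table)
  rm_ <- rowMeans(table); cm_ <- colMeans(table)
  ssr <- k * sum((rm_ - grand)^2)
  ssc <- n * sum((cm_ - grand)^2)
  sst <- sum((table - grand)^2)
  sse <- max(0, sst - ssr - ssc)
  msr <- ssr / (n - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (mse <= .Machine$double.eps * max(msr, 1)) {
    return(list(icc = 1, lo = NA_real_, hi = NA_real_, ms_rows = msr,
                ms_error = mse, n = n, k = k, degenerate = TRUE))
  }
  icc <- (msr - mse) / msr
  Fobs <- msr / mse
  a <- (1 - conf) / 2
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  FL <- Fobs / stats::qf(1 - a, df1, df2)
  FU <- Fobs * stats::qf(1 - a, df2, df1)
  list(icc = icc, lo = 1 - 1 / FL, hi = 1 - 1 / FU,
       ms_rows = msr, ms_error = mse, n = n, k = k, degenerate = FALSE)
}

#' Qualitative reproducibility classification of an ICC
#'
#' Bands: above 0.75 excellent; 0.6-0.75 good; 0.40-0.60 fair; below 0.40
#' (including negative estimates) poor. The boundary value 0.75 itself is
#' assigned to "good".
#'
#' @param icc finite ICC value(s).
#' @return character vector of labels.
#' @export
classify_icc <- function(icc) {
  if (any(!is.finite(icc))) stop("non-finite ICC")
  out <- character(length(icc))
  out[icc > 0.75] <- "excellent"
  out[icc <= 0.75 & icc >= 0.6] <- "good"
  out[icc < 0.6 & icc >= 0.4] <- "fair"
  out[icc < 0.4] <- "poor"
  out
}

#' Precision errors across repeat scans
#'
#' Per-subject standard deviation over repeats (denominator k-1);
#' `PE(SD)` is the root mean square of the per-subject SDs and `PE(%CV)`
#' the root mean square of the per-subject coefficients of variation,
#' times 100.
#'
#' @param table numeric matrix, subjects x repeats.
#' @return list with `pe_sd` (metric units) and `pe_cv` (percent;
#'   `NA` with a warning if any subject mean is not positive).
#' @export
precision_error <- function(table) {
  table <- as.matrix(table)
  if (ncol(table) < 2) stop("need at least 2 repeats")
  sds <- apply(table, 1, stats::sd)
  means <- rowMeans(table)
  pe_sd <- sqrt(mean(sds^2))
  if (any(means <= 0)) {
    warning("non-positive subject mean: PE(%CV) undefined")
    pe_cv <- NA_real_
  } else {
    pe_cv <- sqrt(mean((sds / means)^2)) * 100
  }
  list(pe_sd = pe_sd, pe_cv = pe_cv)
}

#' RMSE and mean-normalised RMSE against a reference
#'
#' @param reference,test numeric vectors of equal length; `reference` is
#'   the gold standard (e.g. the manual measurements).
#' @return list with `rmse` (units of the input) and `nrmse` (percent of
#'   the reference mean).
#' @export
rmse_nrmse <- function(reference, test) {
  if (length(reference) != length(test) || length(reference) < 1)
    stop("reference and test must have equal positive length")
  rmse <- sqrt(mean((test - reference)^2))
  mr <- mean(reference)
  if (mr == 0) stop("zero reference mean: NRMSE undefined")
  list(rmse = rmse, nrmse = rmse / mr * 100)
}

#' Reproducibility report across repeat scans
#'
#' Builds, for each metric column, the subjects x repeats table (subjects
#' with missing repeats are dropped with a message) and reports ICC(C,k)
#' with its 95% interval, precision errors and the qualitative
#' classification, mirroring the standard report layout
#' (metric, ICC, Lower95, Upper95, PE_SD, PE_pctCV, classification).
#'
#' @param results long data frame of per-scan measurements.
#' @param metrics character vector of metric column names in `results`.
#' @param subject,repeat_col names of the subject and repeat id columns.
#' @return data frame, one row per metric.
#' @export
repro_report <- function(results, metrics, subject = "sample_id",
                         repeat_col = "repeat_id") {
  rows <- lapply(metrics, function(mname) {
    v <- results[[mname]]
    tab <- tapply(v, list(results[[subject]], results[[repeat_col]]),
                  function(x) mean(x))
    ok <- stats::complete.cases(tab)
    if (any(!ok))
      message(sprintf("%s: dropping %d subject(s) with missing repeats",
                      mname, sum(!ok)))
    tab <- tab[ok, , drop = FALSE]
    if (nrow(tab) < 2)
      return(data.frame(metric = mname, ICC = NA_real_, Lower95 = NA_real_,
                        Upper95 = NA_real_, PE_SD = NA_real_,
                        PE_pctCV = NA_real_, classification = NA_character_))
    ic <- icc_consistency(tab)
    pe <- suppressWarnings(precision_error(tab))
    data.frame(metric = mname, ICC = ic$icc, Lower95 = ic$lo,
               Upper95 = ic$hi, PE_SD = pe$pe_sd, PE_pctCV = pe$pe_cv,
               classification = classify_icc(ic$icc),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
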