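# Measurement-agreement statistics for repeated-measurement designs:
# ICC(2,1) (two-way random effects, single measurement, absolute agreement)
# with the Shrout-Fleiss / McGraw-Wong F-based 95% CI, Dahlberg's error,
# Bland-Altman limits of agreement, the paired t-test, ICC category bands,
# and the 1 mm / 1.5 degree systematic-error gates.

#' Intraclass correlation ICC(2,1): two-way random, single measurement,
#' absolute agreement
#'
#' Computed from the two-way ANOVA mean squares (subjects MSR, raters MSC,
#' error MSE) as
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`,
#' with the F-distribution confidence interval of Shrout & Fleiss /
#' McGraw & Wong. Deterministic; zero total variance is a typed error, not
#' a silent `NaN`.
#'
#' @param x An `n x k` numeric matrix (subjects x measurements) with no
#'   missing cells, or a long data frame with subject/rater/value columns.
#' @param subject,rater,value For the data-frame method: column names
#'   (character) holding the subject id, the measurement/rater label and the
#'   value.
#' @param alpha Confidence level is `1 - alpha` (default 0.05, the 95% CI).
#' @param ... Passed between methods.
#' @return An object of class `icc_fit`: a list with `icc`, `ci_low`,
#'   `ci_high`, `category` (see [classify_icc()]), mean squares, `n`, `k`,
#'   `alpha`. Has [tidy()][generics::tidy] and [glance()][generics::glance]
#'   methods.
#' @export
#' @examples
#' m <- cbind(first = c(9, 6, 8, 7, 10), second = c(9.1, 6.3, 7.9, 7.1, 9.8))
#' icc_2_1(m)
icc_2_1 <- function(x, ...) UseMethod("icc_2_1")

#' @rdname icc_2_1
#' @export
icc_2_1.matrix <- function(x, alpha = 0.05, ...) {
  if (anyNA(x)) stop("rater matrix must have no missing cells", call. = FALSE)
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) {
    stop("need at least 2 subjects and 2 measurements (got n = ", n,
         ", k = ", k, ")", call. = FALSE)
  }
  if (stats::var(as.numeric(x)) == 0) {
    stop("undefined ICC: all cells are identical (zero total variance)",
         call. = FALSE)
  }
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)        # subjects
  ssc <- n * sum((col_m - grand)^2)        # raters / measurements
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc                   # residual
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  # McGraw & Wong (1996) CI for ICC(A,1)
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fl <- stats::qf(1 - alpha / 2, n - 1, v)
  fu <- stats::qf(1 - alpha / 2, v, n - 1)
  ci_low <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  ci_high <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)

  structure(list(icc = icc, ci_low = ci_low, ci_high = ci_high,
                 category = classify_icc(max(-1, min(1, icc))),
                 msr = msr, msc = msc, mse = mse,
                 n = n, k = k, alpha = alpha),
            class = "icc_fit")
}

#' @rdname icc_2_1
#' @export
icc_2_1.data.frame <- function(x, subject = "subject", rater = "rater",
                               value = "value", alpha = 0.05, ...) {
  wide <- tidyr::pivot_wider(x[c(subject, rater, value)],
                             names_from = dplyr::all_of(rater),
                             values_from = dplyr::all_of(value))
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- as.character(wide[[1]])
  icc_2_1(m, alpha = alpha)
}

#' @export
print.icc_fit <- function(x, ...) {
  cat(sprintf("ICC(2,1) absolute agreement: %.4f  %d%% CI [%.4f, %.4f]  (%s)\n",
              x$icc, round(100 * (1 - x$alpha)), x$ci_low, x$ci_high,
              x$category))
  cat(sprintf("  n = %d subjects, k = %d measurements\n", x$n, x$k))
  invisible(x)
}

#' Dahlberg's error of the method
#'
#' `D = sqrt(sum((first - second)^2) / (2 n))` over paired repeated
#' measurements; the classical method-error statistic, in the units of the
#' input.
#'
#' @param first,second Equal-length numeric vectors of paired repeats.
#' @return The Dahlberg error (non-negative scalar).
#' @export
#' @examples
#' dahlberg_error(c(1, 2), c(2, 3))  # sqrt(2/4)
dahlberg_error <- function(first, second) {
  if (length(first) != length(second)) {
    stop("first and second must have the same length (", length(first),
         " vs ", length(second), ")", call. = FALSE)
  }
  if (length(first) < 1) stop("need at least one pair", call. = FALSE)
  d <- first - second
  sqrt(sum(d^2) / (2 * length(d)))
}

#' Bland-Altman agreement analysis
#'
#' Bias is the mean of the paired differences; the limits of agreement are
#' `bias +/- k_sigma * SD(diff)` with the sample (n-1) standard deviation.
#'
#' @param first,second Equal-length numeric vectors, `n >= 2`.
#' @param k_sigma Multiplier for the limits of agreement (default 1.96).
#' @return An object of class `bland_altman`: `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `k_sigma`, `n`, and a `data` tibble of per-pair means and
#'   differences for plotting. Has `tidy()`, `glance()` and `autoplot()`
#'   methods.
#' @export
#' @examples
#' ba <- bland_altman(c(1, 3, 2, 5), c(1, 1, 2, 4))
#' ba$bias
bland_altman <- function(first, second, k_sigma = 1.96) {
  if (length(first) != length(second)) {
    stop("first and second must have the same length", call. = FALSE)
  }
  n <- length(first)
  if (n < 2) stop("Bland-Altman needs at least 2 pairs", call. = FALSE)
  d <- first - second
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  structure(list(
    bias = bias, sd_diff = sd_diff,
    loa_low = bias - k_sigma * sd_diff, loa_high = bias + k_sigma * sd_diff,
    k_sigma = k_sigma, n = n,
    data = tibble::tibble(mean = (first + second) / 2, diff = d)),
    class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.4f, SD %.4f, LoA [%.4f, %.4f]\n",
              x$n, x$bias, x$sd_diff, x$loa_low, x$loa_high))
  invisible(x)
}

#' Paired two-sided t-test on repeated measurements
#'
#' Thin wrapper over [stats::t.test()] (paired, two-sided, `n - 1` df). For
#' identical vectors the difference variance is zero and the t statistic is
#' undefined; by convention the result is flagged (`zero_variance = TRUE`)
#' with `t = 0` and `p = 1`, since no systematic difference is detectable.
#'
#' @param first,second Equal-length numeric vectors, `n >= 2`.
#' @return A list with `t`, `p`, `df`, `mean_diff`, `zero_variance`.
#' @export
#' @examples
#' paired_t_test(c(1, 3), c(0, 0))  # t = 2, df = 1
paired_t_test <- function(first, second) {
  if (length(first) != length(second)) {
    stop("first and second must have the same length", call. = FALSE)
  }
  n <- length(first)
  if (n < 2) stop("paired t-test needs at least 2 pairs", call. = FALSE)
  d <- first - second
  if (stats::sd(d) == 0) {
    return(list(t = 0, p = 1, df = n - 1, mean_diff = mean(d),
                zero_variance = TRUE))
  }
  ht <- stats::t.test(first, second, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter),
       mean_diff = mean(d), zero_variance = FALSE)
}

#' Map an ICC value to its agreement category
#'
#' Bands: `[0.9, 1]` excellent, `[0.6, 0.9)` good, `[0.4, 0.6)` reasonable,
#' `< 0.4` poor. The published band edges leave `0.5-0.6` and `0.7-0.9`
#' unnamed; each gap is absorbed into the band below it so the mapping is
#' total, with boundaries closed on the left of each named band.
#'
#' @param icc Numeric in `[-1, 1]`.
#' @return `"excellent"`, `"good"`, `"reasonable"` or `"poor"`.
#' @export
#' @examples
#' classify_icc(0.95)
#' classify_icc(0.39)
classify_icc <- function(icc) {
  if (!is.finite(icc) || icc < -1 || icc > 1) {
    stop("ICC must be in [-1, 1], got ", icc, call. = FALSE)
  }
  if (icc >= 0.9) "excellent"
  else if (icc >= 0.6) "good"
  else if (icc >= 0.4) "reasonable"
  else "poor"
}

#' Systematic-error gate on the Dahlberg error
#'
#' Pass criteria: linear measurements must not exceed 1 mm; angular
#' measurements must not exceed 1.5 degrees. Bounds are inclusive.
#'
#' @param d Dahlberg error, `>= 0` (mm or degrees per `kind`).
#' @param kind `"linear"` or `"angular"`.
#' @return `TRUE` (pass) or `FALSE` (fail).
#' @export
#' @examples
#' systematic_error_gate(0.3, "linear")   # TRUE
#' systematic_error_gate(1.6, "angular")  # FALSE
systematic_error_gate <- function(d, kind = c("linear", "angular")) {
  kind <- match.arg(kind)
  if (!is.finite(d) || d < 0) {
    stop("Dahlberg error must be a non-negative number, got ", d,
         call. = FALSE)
  }
  d <= if (kind == "linear") 1 else 1.5
}

#' Build a per-tooth reliability table
#'
#' The batch driver behind published agreement tables: for every tooth x
#' movement block of a long repeated-measurements table it computes the
#' mean/SD of each measurement column, ICC(2,1) with 95% CI and category,
#' Dahlberg's error with its systematic-error gate, the paired t-test
#' p-value, and the Bland-Altman bias.
#'
#' @param measurements Long tibble with columns `subject_id`, `tooth_id`,
#'   `movement`, `measurement_label`, `value`, `units`. Exactly two distinct
#'   `measurement_label`s per block are required (the paired design); units
#'   must be consistent within each movement.
#' @param alpha ICC CI level (default 0.05).
#' @return A tibble with one row per tooth x movement: `n`, `mean_1`,
#'   `sd_1`, `mean_2`, `sd_2`, `icc`, `ci_low`, `ci_high`, `icc_category`,
#'   `dahlberg`, `error_gate_pass`, `t_p`, `ba_bias`, `ba_loa_low`,
#'   `ba_loa_high`, `units`.
#' @export
build_reliability_table <- function(measurements, alpha = 0.05) {
  need <- c("subject_id", "tooth_id", "movement", "measurement_label",
            "value", "units")
  missing_cols <- setdiff(need, names(measurements))
  if (length(missing_cols) > 0) {
    stop("measurements table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  measurements <- tibble::as_tibble(measurements)
  units_per_movement <- dplyr::summarise(
    dplyr::group_by(measurements, .data$movement),
    n_units = dplyr::n_distinct(.data$units), .groups = "drop")
  if (any(units_per_movement$n_units > 1)) {
    stop("mixed units within movement(s): ",
         paste(units_per_movement$movement[units_per_movement$n_units > 1],
               collapse = ", "), call. = FALSE)
  }
  blocks <- dplyr::group_split(
    dplyr::group_by(measurements, .data$tooth_id, .data$movement))
  rows <- purrr::map(blocks, function(blk) {
    labels <- sort(unique(blk$measurement_label))
    if (length(labels) != 2) {
      stop("tooth ", blk$tooth_id[1], " / ", blk$movement[1], " has ",
           length(labels), " measurement labels; exactly 2 are required",
           call. = FALSE)
    }
    wide <- tidyr::pivot_wider(
      blk[c("subject_id", "measurement_label", "value")],
      names_from = "measurement_label", values_from = "value")
    if (nrow(wide) < 2) {
      stop("tooth ", blk$tooth_id[1], " / ", blk$movement[1],
           " has fewer than 2 subjects", call. = FALSE)
    }
    v1 <- wide[[labels[1]]]; v2 <- wide[[labels[2]]]
    if (anyNA(v1) || anyNA(v2)) {
      stop("missing cells for tooth ", blk$tooth_id[1], " / ",
           blk$movement[1], call. = FALSE)
    }
    fit <- icc_2_1(cbind(v1, v2), alpha = alpha)
    dd <- dahlberg_error(v1, v2)
    ba <- bland_altman(v1, v2)
    tt <- paired_t_test(v1, v2)
    kind <- if (blk$units[1] %in% c("degrees", "deg")) "angular" else "linear"
    tibble::tibble(
      tooth_id = blk$tooth_id[1], movement = blk$movement[1],
      n = nrow(wide),
      mean_1 = mean(v1), sd_1 = stats::sd(v1),
      mean_2 = mean(v2), sd_2 = stats::sd(v2),
      icc = fit$icc, ci_low = fit$ci_low, ci_high = fit$ci_high,
      icc_category = fit$category,
      dahlberg = dd, error_gate_pass = systematic_error_gate(dd, kind),
      t_p = tt$p,
      ba_bias = ba$bias, ba_loa_low = ba$loa_low, ba_loa_high = ba$loa_high,
      units = blk$units[1])
  })
  dplyr::bind_rows(rows)
}
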