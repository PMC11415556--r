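# Human-machine agreement via the intraclass correlation coefficient in the
# two-way, absolute-agreement, average-measures form (McGraw & Wong's
# ICC(A,k); with fixed raters the mixed- vs random-effects distinction
# changes interpretation, not the estimate). Confidence intervals use the
# F-based interval for the single-measure form with Satterthwaite degrees of
# freedom, Spearman-Brown-stepped up to average measures.

#' Reliability label for an ICC value
#'
#' Conventional bands: below 0.5 poor, 0.5-0.75 moderate, above 0.75 good,
#' above 0.9 excellent.
#'
#' @param icc Numeric ICC value(s).
#' @return Character vector of labels.
#' @export
reliability_label <- function(icc) {
  ifelse(icc > 0.9, "excellent",
         ifelse(icc > 0.75, "good",
                ifelse(icc >= 0.5, "moderate", "poor")))
}

#' Two-way absolute-agreement average-measures ICC
#'
#' Decomposes an n-subjects-by-k-raters matrix by two-way ANOVA (subjects
#' and raters as crossed factors) and returns the absolute-agreement
#' average-measures estimate
#' `ICC = (MSR - MSE) / (MSR + (MSC - MSE) / n)`,
#' where MSR, MSC and MSE are the subject, rater and residual mean squares.
#' The 95% confidence interval is the F-distribution interval for this form.
#'
#' @param m Numeric matrix, n subjects (rows) by k raters (columns), no
#'   missing cells, n >= 3, k >= 2.
#' @param conf_level Confidence level for the interval.
#' @param index Optional name of the quantitative index being rated.
#' @return A list of class `"icc_result"`: `icc`, `ci_low`, `ci_high`,
#'   `ms_rows`, `ms_cols`, `ms_error`, `n`, `k`, `reliability_label`,
#'   `index`.
#' @export
icc_absolute_agreement_avg <- function(m, conf_level = 0.95, index = NA_character_) {
  m <- as.matrix(m)
  if (anyNA(m)) {
    keep <- stats::complete.cases(m)
    m <- m[keep, , drop = FALSE]
  }
  n <- nrow(m); k <- ncol(m)
  if (k < 2L) stop("insufficient data: at least two raters required", call. = FALSE)
  if (n < 3L) stop("insufficient data: at least three subjects required", call. = FALSE)

  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (ss_total <= .Machine$double.eps * length(m))
    stop("degenerate variance: ratings are constant, ICC undefined", call. = FALSE)

  icc_k <- (msr - mse) / (msr + (msc - mse) / n)
  icc_1 <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  # Satterthwaite df for the denominator of the single-measure interval
  alpha <- 1 - conf_level
  a <- (k * icc_1) / (n * (1 - icc_1))
  b <- 1 + (k * icc_1 * (n - 1)) / (n * (1 - icc_1))
  v <- (a * msc + b * mse)^2 /
       ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fl <- stats::qf(1 - alpha / 2, n - 1, v)
  fu <- stats::qf(1 - alpha / 2, v, n - 1)
  lo1 <- n * (msr - fl * mse) /
         (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi1 <- n * (fu * msr - mse) /
         (k * msc + (k * n - k - n) * mse + n * fu * msr)
  sb <- function(r) k * r / (1 + (k - 1) * r)   # Spearman-Brown step-up
  # perfect agreement (MSE = 0) degenerates the F bounds; the interval
  # collapses onto the point estimate
  lo1 <- if (is.finite(lo1)) lo1 else icc_1
  hi1 <- if (is.finite(hi1)) hi1 else icc_1
  ci <- sort(c(sb(lo1), sb(hi1)))

  structure(list(icc = icc_k,
                 ci_low = min(ci[1L], icc_k), ci_high = max(ci[2L], icc_k),
                 ms_rows = msr, ms_cols = msc, ms_error = mse,
                 n = n, k = k,
                 reliability_label = reliability_label(icc_k),
                 index = index),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,%d)%s = %.4f (95%% CI %.4f-%.4f), n = %d: %s\n",
              x$k, if (is.na(x$index)) "" else paste0(" [", x$index, "]"),
              x$icc, x$ci_low, x$ci_high, x$n, x$reliability_label))
  invisible(x)
}

# The eleven quantitative indices, by view.
AP_INDICES <- c("XA", "YA", "S17", "S27", "Y3", "Y4", "Y5", "Y6")
LAT_INDICES <- c("X2", "Y2", "alpha")

#' Paired rating matrices for every quantitative index
#'
#' Pairs two report lists (e.g. model vs human) by `image_id` within
#' matching views and builds one n-by-2 rating matrix per quantitative
#' index: eight AP indices (XA, YA, S17, S27, Y3..Y6) from AP pairs and
#' three LAT indices (X2, Y2, alpha) from LAT pairs. Pairs missing from
#' either side are dropped and counted.
#'
#' @param model_reports,human_reports Lists of `"qc_report"` objects.
#' @param rater_labels Column labels for the two raters.
#' @return List with `matrices` (named list of n-by-2 matrices), `n_ap`,
#'   `n_lat`, `dropped` (image ids present on only one side or with
#'   mismatched views).
#' @export
paired_index_table <- function(model_reports, human_reports,
                               rater_labels = c("model", "human")) {
  key <- function(rs) vapply(rs, `[[`, character(1L), "image_id")
  mk <- key(model_reports); hk <- key(human_reports)
  common <- intersect(mk, hk)
  dropped <- union(setdiff(mk, hk), setdiff(hk, mk))
  mi <- match(common, mk); hi <- match(common, hk)
  same_view <- vapply(seq_along(common), function(j)
    model_reports[[mi[j]]]$view == human_reports[[hi[j]]]$view, logical(1L))
  dropped <- c(dropped, common[!same_view])
  common <- common[same_view]; mi <- mi[same_view]; hi <- hi[same_view]
  if (!length(common))
    stop("empty input: no overlapping image ids between the two report sets",
         call. = FALSE)

  views <- vapply(mi, function(i) model_reports[[i]]$view, character(1L))
  build <- function(idx_names, which_view) {
    sel <- views == which_view
    lapply(stats::setNames(idx_names, idx_names), function(nm) {
      mat <- cbind(
        vapply(mi[sel], function(i) model_reports[[i]]$metrics[[nm]], numeric(1L)),
        vapply(hi[sel], function(i) human_reports[[i]]$metrics[[nm]], numeric(1L)))
      dimnames(mat) <- list(common[sel], rater_labels)
      mat
    })
  }
  ap <- if (any(views == "AP")) build(AP_INDICES, "AP") else list()
  lat <- if (any(views == "LAT")) build(LAT_INDICES, "LAT") else list()
  list(matrices = c(ap, lat),
       n_ap = sum(views == "AP"), n_lat = sum(views == "LAT"),
       dropped = dropped)
}

#' Agreement table across quantitative indices
#'
#' One row per index with the ICC point estimate, its 95% confidence
#' interval and the reliability label, plus the raw paired values for
#' scatter-style model-vs-human comparison plots.
#'
#' @param results Nonempty list of `"icc_result"` objects (e.g. one per
#'   index from [icc_absolute_agreement_avg()]), or the output of
#'   [paired_index_table()] (in which case the ICCs are computed here).
#' @param scatter Logical; include the paired raw values per index.
#' @param paired Optional [paired_index_table()] output supplying scatter
#'   data when `results` is a list of `"icc_result"`.
#' @return List with `table` (data frame: index, n, icc, ci_low, ci_high,
#'   label) and, if available, `scatter` (data frame: index, image_id,
#'   rater1, rater2).
#' @export
agreement_report <- function(results, scatter = TRUE, paired = NULL) {
  if (!is.null(results$matrices)) {
    paired <- results
    results <- lapply(names(paired$matrices), function(nm)
      icc_absolute_agreement_avg(paired$matrices[[nm]], index = nm))
  }
  if (!length(results)) stop("empty input: no ICC results", call. = FALSE)
  stopifnot(all(vapply(results, inherits, logical(1L), "icc_result")))
  tab <- do.call(rbind, lapply(results, function(r)
    data.frame(index = r$index, n = r$n, icc = r$icc,
               ci_low = r$ci_low, ci_high = r$ci_high,
               label = r$reliability_label, stringsAsFactors = FALSE)))
  out <- list(table = tab)
  if (scatter && !is.null(paired)) {
    out$scatter <- do.call(rbind, lapply(names(paired$matrices), function(nm) {
      m <- paired$matrices[[nm]]
      data.frame(index = nm, image_id = rownames(m),
                 rater1 = m[, 1L], rater2 = m[, 2L],
                 row.names = NULL, stringsAsFactors = FALSE)
    }))
  }
  out
}
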