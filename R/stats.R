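#' Reader response set
#'
#' Records of a blinded reader study in which radiologists judge whether a
#' displayed nodule is a 3D-printed phantom or a real patient nodule. The
#' positive class throughout is "printed": a false negative is a printed
#' nodule judged to be real — the error that indicates phantom realism.
#'
#' @param df data frame with columns `reader_id`, `experience`
#'   (`"senior"` or `"resident"`), `case_id`, `presentation` (1..3),
#'   `truth` and `call` (`"printed"` or `"patient"`), `confidence`
#'   (integer 1..5).
#' @return the validated data frame with class `response_set`.
#' @export
response_set <- function(df) {
  req <- c("reader_id", "experience", "case_id", "presentation",
           "truth", "call", "confidence")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("response set lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(df$truth %in% c("printed", "patient")) ||
      !all(df$call %in% c("printed", "patient")))
    stop("truth and call must be 'printed' or 'patient'", call. = FALSE)
  if (!all(df$experience %in% c("senior", "resident")))
    stop("experience must be 'senior' or 'resident'", call. = FALSE)
  if (!all(df$confidence %in% 1:5))
    stop("confidence must be an integer in 1..5", call. = FALSE)
  if (!all(df$presentation %in% 1:3))
    stop("presentation must be in 1..3", call. = FALSE)
  class(df) <- unique(c("response_set", class(df)))
  df
}

#' Read / write reader responses as CSV
#' @param path CSV path with the [response_set()] schema.
#' @return a `response_set` (for `read_responses`).
#' @export
read_responses <- function(path) {
  response_set(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_responses
#' @param responses a [response_set()].
#' @export
write_responses <- function(responses, path) {
  utils::write.csv(as.data.frame(responses), path, row.names = FALSE)
  invisible(path)
}

#' Confusion matrix (positive class = 3D-printed)
#'
#' @param tp,fp,fn,tn non-negative counts: tp = printed called printed,
#'   fp = patient called printed, fn = printed called patient, tn =
#'   patient called patient.
#' @return an object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (sum(counts) == 0) stop("confusion matrix is empty", call. = FALSE)
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2L, byrow = TRUE,
              dimnames = list(c("called printed", "called patient"),
                              c("printed", "patient")))
  cat(sprintf("confusion matrix (n = %d):\n", x$tp + x$fp + x$fn + x$tn))
  print(m)
  invisible(x)
}

#' Tabulate a confusion matrix from reader responses
#'
#' @param responses a [response_set()].
#' @param experience optional filter: `"senior"` or `"resident"`.
#' @return a [confusion_matrix()].
#' @export
tabulate_confusion <- function(responses, experience = NULL) {
  df <- as.data.frame(responses)
  if (!is.null(experience)) df <- df[df$experience == experience, ]
  if (nrow(df) == 0L) stop("no responses after filtering", call. = FALSE)
  confusion_matrix(
    tp = sum(df$truth == "printed" & df$call == "printed"),
    fp = sum(df$truth == "patient" & df$call == "printed"),
    fn = sum(df$truth == "printed" & df$call == "patient"),
    tn = sum(df$truth == "patient" & df$call == "patient"))
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up (the convention of the reported
#' contingency tables), unlike R's banker's rounding.
#'
#' @param x numeric.
#' @param digits decimal digits.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' Classification rates from a confusion matrix
#'
#' Accuracy, true/false positive/negative rates as percentages rounded
#' half-up to one decimal. A class-conditional rate whose class is absent
#' is reported as `NA` (undefined), never as 0.
#'
#' @param cm a [confusion_matrix()].
#' @return an object of class `rate_summary` with fields `accuracy`,
#'   `tpr`, `tnr`, `fpr`, `fnr` (percent) and the raw `counts`.
#' @export
classification_rates <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$fp + cm$fn + cm$tn
  pos <- cm$tp + cm$fn
  neg <- cm$tn + cm$fp
  pct <- function(num, den) if (den > 0) round_half_up(100 * num / den, 1)
  else NA_real_
  structure(list(
    accuracy = pct(cm$tp + cm$tn, total),
    tpr = pct(cm$tp, pos), fnr = pct(cm$fn, pos),
    tnr = pct(cm$tn, neg), fpr = pct(cm$fp, neg),
    counts = cm), class = "rate_summary")
}

#' @export
print.rate_summary <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%", v)
  cat("Overall accuracy    ", fmt(x$accuracy), "\n")
  cat("True positive rate  ", fmt(x$tpr), "\n")
  cat("True negative rate  ", fmt(x$tnr), "\n")
  cat("False negative rate ", fmt(x$fnr), "\n")
  cat("False positive rate ", fmt(x$fpr), "\n")
  invisible(x)
}

rate_value <- function(df, metric) {
  tp <- sum(df$truth == "printed" & df$call == "printed")
  fp <- sum(df$truth == "patient" & df$call == "printed")
  fn <- sum(df$truth == "printed" & df$call == "patient")
  tn <- sum(df$truth == "patient" & df$call == "patient")
  pos <- tp + fn; neg <- tn + fp; total <- pos + neg
  switch(metric,
    accuracy = if (total > 0) 100 * (tp + tn) / total else NA_real_,
    tpr = if (pos > 0) 100 * tp / pos else NA_real_,
    fnr = if (pos > 0) 100 * fn / pos else NA_real_,
    tnr = if (neg > 0) 100 * tn / neg else NA_real_,
    fpr = if (neg > 0) 100 * fp / neg else NA_real_,
    stop("unknown metric: ", metric, call. = FALSE))
}

#' Bootstrap confidence interval for a classification rate
#'
#' Percentile bootstrap over resamples drawn with replacement at the
#' chosen unit. Response-level resampling treats every reading as
#' independent; reader- and case-level resampling respect the clustering
#' of readings within radiologists or nodule acquisitions, which widens
#' the interval when readings are correlated.
#'
#' @param responses a [response_set()].
#' @param metric one of `"accuracy"`, `"tpr"`, `"tnr"`, `"fpr"`, `"fnr"`.
#' @param unit resampling unit: `"response"`, `"reader"` or `"case"`.
#' @param B number of bootstrap replicates (>= 100).
#' @param seed RNG seed.
#' @param conf confidence level.
#' @param max_redraw cap on redraws of degenerate resamples (resamples on
#'   which the metric is undefined).
#' @return numeric length-2 `c(lo, hi)` in percent.
#' @export
bootstrap_ci <- function(responses, metric = "accuracy",
                         unit = c("response", "reader", "case"),
                         B = 5000, seed = NULL, conf = 0.95,
                         max_redraw = 100L) {
  unit <- match.arg(unit)
  stopifnot(B >= 100)
  df <- as.data.frame(responses)
  if (!is.null(seed)) set.seed(seed)
  is_pos <- df$truth == "printed"
  called_pos <- df$call == "printed"
  ids <- switch(unit,
    response = seq_len(nrow(df)),
    reader = df$reader_id,
    case = df$case_id)
  uids <- unique(ids)
  rows_by_uid <- if (unit == "response") NULL else
    lapply(uids, function(u) which(ids == u))
  metric_fun <- function(rows) {
    pos <- is_pos[rows]; cp <- called_pos[rows]
    tp <- sum(pos & cp); fp <- sum(!pos & cp)
    fn <- sum(pos & !cp); tn <- sum(!pos & !cp)
    np <- tp + fn; nn <- tn + fp
    switch(metric,
      accuracy = 100 * (tp + tn) / (np + nn),
      tpr = if (np > 0) 100 * tp / np else NA_real_,
      fnr = if (np > 0) 100 * fn / np else NA_real_,
      tnr = if (nn > 0) 100 * tn / nn else NA_real_,
      fpr = if (nn > 0) 100 * fp / nn else NA_real_,
      stop("unknown metric: ", metric, call. = FALSE))
  }
  stat <- numeric(B)
  for (b in seq_len(B)) {
    for (attempt in seq_len(max_redraw + 1L)) {
      take <- sample.int(length(uids), length(uids), replace = TRUE)
      rows <- if (unit == "response") take else
        unlist(rows_by_uid[take], use.names = FALSE)
      v <- metric_fun(rows)
      if (!is.na(v)) break
      if (attempt > max_redraw)
        stop("degenerate bootstrap resamples: metric undefined after ",
             max_redraw, " redraws", call. = FALSE)
    }
    stat[b] <- v
  }
  alpha <- (1 - conf) / 2
  as.numeric(stats::quantile(stat, c(alpha, 1 - alpha), names = FALSE))
}

#' Conger's kappa for multiple raters
#'
#' Exact multi-rater generalisation of Cohen's kappa:
#' `kappa = (Po - Pe) / (1 - Pe)` with `Po` the mean pairwise agreement
#' over items and `Pe` the mean over ordered rater pairs of the inner
#' product of the two raters' category marginals. For two raters this is
#' exactly Cohen's kappa.
#'
#' @param ratings matrix or data frame, items x raters; any atomic
#'   category coding, no missing cells.
#' @return an object of class `kappa_result` with fields `kappa` (`NA`
#'   when chance agreement is 1 and kappa undefined), `po`, `pe`,
#'   `n_raters`, `n_items`, `n_categories`.
#' @export
conger_kappa <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); R <- ncol(ratings)
  if (n < 2L || R < 2L)
    stop("need at least 2 items and 2 raters", call. = FALSE)
  if (anyNA(ratings)) stop("missing cells not supported", call. = FALSE)
  cats <- sort(unique(as.vector(ratings)))
  K <- length(cats)
  idx <- matrix(match(ratings, cats), n, R)
  # observed: mean over items of pairwise agreement
  counts <- matrix(0L, n, K)
  for (c_ in seq_len(K)) counts[, c_] <- rowSums(idx == c_)
  po <- mean(rowSums(counts * (counts - 1L)) / (R * (R - 1L)))
  # chance: mean over rater pairs of marginal products
  pmarg <- matrix(0, R, K)
  for (c_ in seq_len(K)) pmarg[, c_] <- colMeans(idx == c_)
  colsum <- colSums(pmarg)
  pe <- sum(colsum^2 - colSums(pmarg^2)) / (R * (R - 1L))
  kap <- if (abs(1 - pe) < 1e-12) NA_real_ else (po - pe) / (1 - pe)
  structure(list(kappa = kap, po = po, pe = pe,
                 n_raters = R, n_items = n, n_categories = K),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  if (is.na(x$kappa))
    cat("Conger's kappa: undefined (chance agreement = 1)\n")
  else
    cat(sprintf("Conger's kappa: %.4f (Po = %.4f, Pe = %.4f; %d raters, %d items)\n",
                x$kappa, x$po, x$pe, x$n_raters, x$n_items))
  invisible(x)
}

#' Chi-square goodness-of-fit test for binary correctness
#'
#' Tests observed (correct, incorrect) counts against an expected
#' correct proportion; the default null `null_p = 0.5` is guessing, under
#' which failure to reject means readers cannot distinguish printed from
#' real nodules.
#'
#' @param correct,incorrect observed counts.
#' @param null_p expected correct proportion under the null, in (0, 1).
#' @return an object of class `gof_result` with `statistic`, `df`,
#'   `p_value`, `null_spec`.
#' @export
chi2_goodness_of_fit <- function(correct, incorrect, null_p = 0.5) {
  if (correct < 0 || incorrect < 0)
    stop("counts must be non-negative", call. = FALSE)
  n <- correct + incorrect
  if (n <= 0) stop("no observations", call. = FALSE)
  if (null_p <= 0 || null_p >= 1)
    stop("null_p must lie strictly in (0, 1)", call. = FALSE)
  e <- c(n * null_p, n * (1 - null_p))
  if (any(e == 0)) stop("zero expected count", call. = FALSE)
  o <- c(correct, incorrect)
  stat <- sum((o - e)^2 / e)
  structure(list(statistic = stat, df = 1L,
                 p_value = stats::pchisq(stat, 1L, lower.tail = FALSE),
                 null_spec = sprintf("P(correct) = %g", null_p)),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("chi-square goodness of fit: X^2 = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  cat("  null:", x$null_spec, "\n")
  invisible(x)
}

#' Confidence-level summary with likelihood ratios
#'
#' For each Likert confidence level 1..5: the response count, its
#' proportion within correct and within incorrect responses, and the
#' likelihood ratio of the two proportions. A ratio whose denominator
#' group lacks the level is reported as `NA` (undefined), never as an
#' infinite number.
#'
#' @param responses a [response_set()].
#' @return data frame with columns `confidence`, `n`, `n_correct`,
#'   `n_incorrect`, `prop_correct`, `prop_incorrect`, `lr`.
#' @export
confidence_summary <- function(responses) {
  df <- as.data.frame(responses)
  correct <- df$call == df$truth
  n_cor <- sum(correct); n_inc <- sum(!correct)
  out <- data.frame(confidence = 1:5)
  out$n <- vapply(1:5, function(l) sum(df$confidence == l), 0L)
  out$n_correct <- vapply(1:5, function(l)
    sum(df$confidence == l & correct), 0L)
  out$n_incorrect <- out$n - out$n_correct
  out$prop_correct <- if (n_cor > 0) out$n_correct / n_cor else NA_real_
  out$prop_incorrect <- if (n_inc > 0) out$n_incorrect / n_inc else NA_real_
  out$lr <- ifelse(!is.na(out$prop_incorrect) & out$prop_incorrect > 0,
                   out$prop_correct / out$prop_incorrect, NA_real_)
  out
}
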