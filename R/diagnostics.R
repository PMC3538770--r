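#' 2x2 contingency table of an index test against a gold standard
#'
#' @param tp,fn,fp,tn nonnegative integer counts: true positive, false
#'   negative, false positive, true negative (index test vs gold standard).
#' @return object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (sum(counts) == 0) stop("table total must be > 0", call. = FALSE)
  counts <- as.integer(counts)
  structure(list(tp = counts[1], fn = counts[2], fp = counts[3],
                 tn = counts[4]),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(gold = c("positive", "negative"),
                              index = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' @export
as.matrix.contingency_2x2 <- function(x, ...) {
  matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE)
}

# Clopper-Pearson exact interval for x successes out of n.
clopper_pearson <- function(x, n, conf_level = 0.95) {
  a <- (1 - conf_level) / 2
  lower <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(lower = lower, upper = upper)
}

#' Diagnostic accuracy metrics from a 2x2 table
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), accuracy (tp+tn)/total,
#' PPV tp/(tp+fp) and NPV tn/(tn+fn), each with an exact Clopper-Pearson
#' confidence interval. A metric whose denominator is zero is reported as
#' `NA` with a warning, never coerced to a number.
#'
#' @param t a [contingency_2x2()].
#' @param conf_level confidence level for the exact intervals.
#' @return object of class `diagnostic_metrics`: list of five metric entries
#'   (`estimate`, `lower`, `upper`, `numerator`, `denominator`) plus `table`.
#' @export
diagnostic_metrics <- function(t, conf_level = 0.95) {
  stopifnot(inherits(t, "contingency_2x2"))
  total <- t$tp + t$fn + t$fp + t$tn
  one <- function(num, den, name) {
    if (den == 0) {
      warning(name, " undefined: zero denominator", call. = FALSE)
      return(list(estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                  numerator = num, denominator = den))
    }
    ci <- clopper_pearson(num, den, conf_level)
    list(estimate = num / den, lower = ci[["lower"]], upper = ci[["upper"]],
         numerator = num, denominator = den)
  }
  structure(
    list(
      sensitivity = one(t$tp, t$tp + t$fn, "sensitivity"),
      specificity = one(t$tn, t$tn + t$fp, "specificity"),
      accuracy    = one(t$tp + t$tn, total, "accuracy"),
      ppv         = one(t$tp, t$tp + t$fp, "ppv"),
      npv         = one(t$tn, t$tn + t$fn, "npv"),
      table = t
    ),
    class = "diagnostic_metrics"
  )
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  for (m in c("sensitivity", "specificity", "accuracy", "ppv", "npv")) {
    e <- x[[m]]
    if (is.na(e$estimate)) {
      cat(sprintf("%-12s undefined (0 denominator)\n", m))
    } else {
      cat(sprintf("%-12s %5.1f%% (%d/%d; 95%% CI %.1f-%.1f%%)\n", m,
                  percent_1dp(e$estimate), e$numerator, e$denominator,
                  100 * e$lower, 100 * e$upper))
    }
  }
  invisible(x)
}

#' Round a proportion to a one-decimal percentage, half away from zero
#'
#' The display convention for all reported percentages (82.6, 1.9, 13.6,
#' 75.0, 74.0, ...).
#'
#' @param p proportion in \[0, 1\].
#' @return percentage rounded to one decimal.
#' @export
percent_1dp <- function(p) {
  x <- 100 * p
  sign(x) * floor(abs(x) * 10 + 0.5) / 10
}

#' Detection rate with exact binomial confidence interval
#'
#' @param detected,total nonnegative counts, `detected <= total`, `total > 0`.
#' @param conf_level confidence level.
#' @return list with `proportion`, `percent` (one-decimal, half away from
#'   zero), `lower`, `upper`, `detected`, `total`.
#' @export
detection_rate <- function(detected, total, conf_level = 0.95) {
  if (total <= 0) stop("`total` must be > 0", call. = FALSE)
  if (detected < 0 || detected > total)
    stop("`detected` must lie in [0, total]", call. = FALSE)
  ci <- clopper_pearson(detected, total, conf_level)
  list(proportion = detected / total,
       percent = percent_1dp(detected / total),
       lower = ci[["lower"]], upper = ci[["upper"]],
       detected = detected, total = total)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Conditional on both margins, the table count follows a hypergeometric
#' distribution. The two-sided p-value is the sum of point probabilities of
#' every table (with the observed margins) whose point probability does not
#' exceed that of the observed table — the point-probability definition used
#' by mainstream statistics software. Probabilities are computed in
#' log-space via `lchoose`, so tables of a few hundred observations pose no
#' overflow risk; ties are admitted within a relative tolerance of 1e-7.
#'
#' @param table a 2x2 matrix of nonnegative integer counts, or a
#'   [contingency_2x2()].
#' @return object of class `fisher_result`: list with `p_two_sided` and
#'   `method`.
#' @export
fisher_exact <- function(table) {
  if (inherits(table, "contingency_2x2")) table <- as.matrix(table)
  if (!is.matrix(table) || !identical(dim(table), c(2L, 2L)))
    stop("`table` must be a 2x2 matrix", call. = FALSE)
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be nonnegative integers", call. = FALSE)
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (n == 0) stop("table total must be > 0", call. = FALSE)
  lp <- function(x) {
    lchoose(r1, x) + lchoose(n - r1, c1 - x) - lchoose(n, c1)
  }
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  logs <- lp(support)
  obs <- lp(a)
  p <- sum(exp(logs[logs <= obs + log(1 + 1e-7)]))
  structure(
    list(p_two_sided = min(p, 1), method = "hypergeometric point-probability"),
    class = "fisher_result"
  )
}

#' @export
print.fisher_result <- function(x, ...) {
  cat(sprintf("Fisher's exact test (two-sided, %s): p = %.6g\n",
              x$method, x$p_two_sided))
  invisible(x)
}

#' Build the study's contingency tables from a cohort table
#'
#' From a long-format cohort table (as produced by [simulate_cohort()] or
#' read from TSV) emits:
#' \describe{
#'   \item{hemorrhage_by_disease}{2x2 matrix of SWI-detected hemorrhage
#'     (yes/no) by disease arm (cancer/BPH), for the association test;}
#'   \item{calcification_swi, calcification_conv_mri}{[contingency_2x2()]
#'     of each modality's calcification detection against the CT gold
#'     standard.}
#' }
#' Every table's total equals the number of patients.
#'
#' @param cohort data.frame with columns `patient_id`, `disease`,
#'   `lesion_kind`, `swi_detected`, `conv_mri_detected`, `ct_detected`.
#' @return named list of tables.
#' @export
build_study_tables <- function(cohort) {
  need <- c("patient_id", "disease", "lesion_kind", "swi_detected",
            "conv_mri_detected", "ct_detected")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols))
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(cohort) == 0) stop("cohort is empty", call. = FALSE)
  hem <- cohort[cohort$lesion_kind == "hemorrhage", ]
  cal <- cohort[cohort$lesion_kind == "calcification", ]
  hem_tab <- matrix(
    c(sum(hem$disease == "cancer" & hem$swi_detected),
      sum(hem$disease == "cancer" & !hem$swi_detected),
      sum(hem$disease == "bph" & hem$swi_detected),
      sum(hem$disease == "bph" & !hem$swi_detected)),
    2, 2, byrow = TRUE,
    dimnames = list(disease = c("cancer", "bph"),
                    hemorrhage = c("detected", "not_detected"))
  )
  vs_ct <- function(idx) {
    gold <- as.logical(cal$ct_detected)
    test <- as.logical(idx)
    contingency_2x2(tp = sum(gold & test), fn = sum(gold & !test),
                    fp = sum(!gold & test), tn = sum(!gold & !test))
  }
  out <- list(hemorrhage_by_disease = hem_tab)
  if (nrow(cal)) {
    out$calcification_swi <- vs_ct(cal$swi_detected)
    out$calcification_conv_mri <- vs_ct(cal$conv_mri_detected)
  }
  out
}
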