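#' Detection proportion from counts
#'
#' @param detected Number of detected changes.
#' @param total Number of trials (or change opportunities).
#' @param digits If not `NULL`, round the reported value (detection
#'   proportions are conventionally printed to 3 decimals).
#' @returns The proportion `detected / total`.
#' @examples
#' detection_proportion(4, 174)         # 0.023
#' detection_proportion(3, 410)         # 0.007
#' @export
detection_proportion <- function(detected, total, digits = 3) {
  if (length(total) != 1 || total <= 0) {
    stop("undefined proportion: total must be a positive count", call. = FALSE)
  }
  if (detected < 0 || detected > total) {
    stop("detected must lie in [0, total]", call. = FALSE)
  }
  p <- detected / total
  if (!is.null(digits)) round(p, digits) else p
}

#' Two-proportion z test (pooled)
#'
#' Tests the difference of two independent proportions with the classical
#' pooled-variance z statistic:
#' `z = (p1 - p2) / sqrt(p(1-p) (1/n1 + 1/n2))` with `p` the pooled
#' proportion, and a two-sided normal p-value `2 * pnorm(-|z|)`. Used to
#' compare detection rates between experiments.
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @returns A one-row tibble: `estimate1`, `estimate2`, `statistic` (z),
#'   `p.value` (two-sided).
#' @examples
#' two_proportion_z(4, 174, 4, 660)
#' @export
two_proportion_z <- function(x1, n1, x2, n2) {
  stopifnot(x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2, n1 > 0, n2 > 0)
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  if (pp <= 0 || pp >= 1) {
    stop("degenerate test: pooled proportion is 0 or 1", call. = FALSE)
  }
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  tibble::tibble(estimate1 = p1, estimate2 = p2, statistic = z,
                 p.value = 2 * stats::pnorm(-abs(z)))
}

#' Paired t test on detection rates
#'
#' Standard paired t on the within-pair differences (`df = n - 1`),
#' wrapping [stats::t.test()]. Defaults to a one-sided test of
#' `mean(a) < mean(b)` because directional contrasts (e.g. adjacent color
#' pairs yielding *lower* detection than distant pairs) are the typical
#' use; both tails are available via `tail`.
#'
#' @param a,b Paired numeric vectors (e.g. per-image detection rates under
#'   two conditions).
#' @param tail `"one"` (default, alternative `a < b`) or `"two"`.
#' @returns A one-row tibble: `estimate` (mean difference a - b),
#'   `statistic` (t), `df`, `p.value`, `tail`.
#' @export
paired_t <- function(a, b, tail = c("one", "two")) {
  tail <- match.arg(tail)
  stopifnot(length(a) == length(b), length(a) >= 2)
  if (stats::var(a - b) == 0) {
    stop("degenerate test: paired differences have zero variance", call. = FALSE)
  }
  ht <- stats::t.test(a, b, paired = TRUE,
                      alternative = if (tail == "one") "less" else "two.sided")
  tibble::tibble(estimate = unname(ht$estimate), statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p.value = ht$p.value, tail = tail)
}

#' One-way repeated-measures ANOVA
#'
#' Fits the within-subject one-way ANOVA via [stats::aov()] with subject as
#' the error stratum: `F = MS_level / MS_(level x subject)` on
#' `df = (k - 1, (k - 1)(n - 1))`. For detection rates of 11 images under
#' 5 color conditions this gives `F(4, 40)`.
#'
#' @param values Numeric `subject x level` matrix (complete; e.g. rows =
#'   images, columns = color conditions), or a data frame coercible to one.
#' @returns A one-row tibble: `statistic` (F), `df1`, `df2`, `p.value`.
#' @export
rm_anova_oneway <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  stopifnot(n >= 2, k >= 2)
  if (anyNA(values)) stop("matrix must be complete (no NA)", call. = FALSE)
  d <- tibble::tibble(
    y = as.vector(values),
    subject = factor(rep(seq_len(n), times = k)),
    level = factor(rep(seq_len(k), each = n)))
  fit <- stats::aov(y ~ level + Error(subject), data = d)
  tab <- summary(fit)[["Error: Within"]][[1L]]
  ms_resid <- tab["Residuals", "Mean Sq"]
  df1 <- tab["level", "Df"]; df2 <- tab["Residuals", "Df"]
  if (ms_resid <= 1e-12) {
    # no residual variance: F is 0/0 when there is also no level effect
    if (tab["level", "Mean Sq"] <= 1e-12) {
      return(tibble::tibble(statistic = 0, df1 = df1, df2 = df2, p.value = 1))
    }
    stop("degenerate ANOVA: zero residual mean square", call. = FALSE)
  }
  tibble::tibble(statistic = tab["level", "F value"],
                 df1 = df1, df2 = df2, p.value = tab["level", "Pr(>F)"])
}

#' Pearson correlation with t-based p-value
#'
#' Wraps [stats::cor.test()]; reports `r`, `r^2` and the two-sided p-value
#' from `t = r sqrt((n-2)/(1-r^2))` on `n - 2` df. Used, e.g., to relate
#' per-video slow-change detection rates to the number of quick changes.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, neither constant.
#' @returns A one-row tibble: `estimate` (r), `r.squared`, `statistic` (t),
#'   `df`, `p.value`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("degenerate correlation: constant input", call. = FALSE)
  }
  ht <- stats::cor.test(x, y)
  tibble::tibble(estimate = unname(ht$estimate),
                 r.squared = unname(ht$estimate)^2,
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p.value = ht$p.value)
}

#' Read a coded trial-response table
#'
#' Reads the CSV produced by manual response coding: one row per trial with
#' `participant_id`, `trial_index` (1-based), `stimulus_id`, `noticed_any`
#' (yes/no or logical), optional `free_text`, logical `slow_detected`,
#' `quick1_detected` ... `quick3_detected` (as many as the stimulus has
#' features; missing columns are treated as no opportunity) and optional
#' `unidentified`. Codes are assigned by a human judge from the free text
#' (a report naming the changed object or its location counts for a quick
#' change; any mention of a change in the slowly changing element counts
#' for the slow change); this function only ingests and validates them.
#'
#' @param path CSV path.
#' @returns A tibble with normalized logical code columns.
#' @export
read_responses <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("participant_id", "trial_index", "stimulus_id", "noticed_any",
            "slow_detected")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0) {
    stop(sprintf("responses CSV lacks column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  to_lgl <- function(v) {
    if (is.logical(v)) return(v)
    tolower(as.character(v)) %in% c("yes", "y", "true", "1")
  }
  code_cols <- intersect(c("noticed_any", "slow_detected", "quick1_detected",
                           "quick2_detected", "quick3_detected", "unidentified"),
                         names(d))
  d <- dplyr::mutate(d, dplyr::across(dplyr::all_of(code_cols), to_lgl))
  bad <- !d$noticed_any &
    rowSums(as.matrix(d[setdiff(code_cols, "noticed_any")]), na.rm = TRUE) > 0
  if (any(bad)) {
    stop(sprintf("%d row(s) carry detection codes but noticed_any is no (first: row %d)",
                 sum(bad), which(bad)[1L]), call. = FALSE)
  }
  tibble::as_tibble(d)
}

#' Aggregate coded responses into a detection table
#'
#' Tallies, per group, the number of trials, detected slow changes,
#' quick-change opportunities and detected quick changes. Group by
#' stimulus, participant, trial position, or any other column.
#'
#' @param responses A tibble from [read_responses()] (or of the same shape).
#' @param ... Grouping columns (tidy-select, e.g. `stimulus_id` or
#'   `trial_index`); empty for a single overall row.
#' @returns A tibble with the grouping keys plus `n_trials`,
#'   `n_slow_detected`, `slow_rate`, `n_quick_opportunities`,
#'   `n_quick_detected`, `quick_rate`.
#' @export
detection_table <- function(responses, ...) {
  qcols <- intersect(paste0("quick", 1:3, "_detected"), names(responses))
  qdet <- if (length(qcols) > 0) {
    rowSums(as.matrix(responses[qcols]), na.rm = TRUE)
  } else rep(0L, nrow(responses))
  qopp <- if (length(qcols) > 0) {
    rowSums(!is.na(as.matrix(responses[qcols])))
  } else rep(0L, nrow(responses))
  responses |>
    dplyr::mutate(.qdet = qdet, .qopp = qopp) |>
    dplyr::group_by(...) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_slow_detected = sum(.data$slow_detected),
      slow_rate = .data$n_slow_detected / .data$n_trials,
      n_quick_opportunities = sum(.data$.qopp),
      n_quick_detected = sum(.data$.qdet),
      quick_rate = ifelse(.data$n_quick_opportunities > 0,
                          .data$n_quick_detected / .data$n_quick_opportunities,
                          NA_real_),
      .groups = "drop")
}

#' Bar plot of detection rates by condition
#'
#' Renders per-condition slow-change detection proportions as bars
#' (optionally with per-item lines), the conventional presentation of
#' change-blindness detection results.
#'
#' @param table A [detection_table()] result.
#' @param condition Column holding the condition (bare name).
#' @returns A ggplot object.
#' @export
plot_detection_rates <- function(table, condition) {
  cond <- rlang::enquo(condition)
  ggplot2::ggplot(table, ggplot2::aes(x = factor(!!cond), y = .data$slow_rate)) +
    ggplot2::geom_col(fill = "#4477aa") +
    ggplot2::labs(x = "condition", y = "proportion of slow changes detected") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
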