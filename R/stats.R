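#' Pairwise linear regression with correlation summary
#'
#' Ordinary least squares of `y` on `x` on raw scales, reporting both the
#' slope and the Pearson correlation coefficient (the two coincide after
#' standardization; both are reported so the significance gate is
#' unambiguous).  The p-value is the two-sided test of zero correlation,
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom —
#' identical to the OLS slope test.
#'
#' @param x,y Numeric vectors of equal length (pairs with missing values
#'   are dropped).
#' @param response,predictor Optional labels carried into the result.
#' @return A one-row tibble of class `comparison_result`: `response`,
#'   `predictor`, `n`, `intercept`, `slope`, `pearson_r`, `r_squared`,
#'   `p_value`, `degenerate` (TRUE when either variable is constant, in
#'   which case the correlation fields are `NA`).
#' @export
linear_regression <- function(x, y, response = "y", predictor = "x") {
  if (length(x) != length(y)) {
    stop("input error: x and y must have equal length", call. = FALSE)
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("input error: need at least 3 complete pairs",
                  call. = FALSE)
  res <- tibble::new_tibble(
    list(response = response, predictor = predictor, n = n,
         intercept = NA_real_, slope = NA_real_, pearson_r = NA_real_,
         r_squared = NA_real_, p_value = NA_real_, degenerate = FALSE),
    nrow = 1L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    res$degenerate <- TRUE
    class(res) <- c("comparison_result", class(res))
    return(res)
  }
  fit <- stats::lm(y ~ x)
  r <- stats::cor(x, y)
  r <- max(min(r, 1), -1)
  tstat <- r * sqrt(n - 2) / sqrt(max(1 - r^2, .Machine$double.eps))
  res$intercept <- unname(stats::coef(fit)[1])
  res$slope <- unname(stats::coef(fit)[2])
  res$pearson_r <- r
  res$r_squared <- r^2
  res$p_value <- 2 * stats::pt(-abs(tstat), df = n - 2)
  class(res) <- c("comparison_result", class(res))
  res
}

#' Two-sample Student's t-test
#'
#' Pooled-variance by default (Welch selectable through the configuration).
#'
#' @param a,b Numeric vectors (missing values dropped), each with >= 2
#'   finite observations.
#' @param cfg A [stats_config()].
#' @return List with `t`, `df`, `p_value`, `mean_a`, `mean_b`, `sd_a`,
#'   `sd_b`, `n_a`, `n_b`.
#' @export
students_ttest <- function(a, b, cfg = stats_config()) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("input error: each group needs at least 2 observations",
         call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = cfg$ttest_variant == "pooled")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value,
       mean_a = mean(a), mean_b = mean(b),
       sd_a = stats::sd(a), sd_b = stats::sd(b),
       n_a = length(a), n_b = length(b))
}

#' Dual significance gate
#'
#' A comparison is significant when its p-value is below `alpha` **and**
#' its r-squared exceeds `r2_min` (defaults 0.05 and 0.11, i.e.
#' `|r| > 0.33`).  Degenerate comparisons are never significant.
#'
#' @param res A one-row `comparison_result` (or anything with `p_value` and
#'   `r_squared` fields).
#' @param cfg A [stats_config()].
#' @return Logical scalar.
#' @export
significance_gate <- function(res, cfg = stats_config()) {
  p <- res$p_value
  r2 <- res$r_squared
  isTRUE(is.finite(p) && is.finite(r2) && p < cfg$alpha && r2 > cfg$r2_min)
}

battery_responses <- function() {
  expand.grid(feature = c("pat", "ptt", "sptt", "s2_over_s1"),
              site = c("finger", "toe"), stringsAsFactors = FALSE)
}

battery_predictors <- function() {
  c("sbp", "dbp", "height", "weight", "bmi", "hr_mean", "vhr", "sex_male",
    "ipa")
}

#' Run the cohort comparison battery
#'
#' Regresses each response — PAT, PTT, SPTT and S2/S1, per site — on each
#' available predictor (SBP, DBP, height, weight, BMI, HR, VHR, sex coded
#' female = 0 / male = 1, and the same-site IPA), with pairwise-complete
#' deletion of missing values, and applies the dual significance gate to
#' every cell.  Missing predictor columns are skipped with a log entry.
#'
#' @param cohort Cohort feature table ([extract_cohort_features()] or
#'   [cohort_truth_table()]).
#' @param cfg A [stats_config()].
#' @return Tidy tibble, one row per comparison cell: `response`,
#'   `predictor`, `n`, `intercept`, `slope`, `pearson_r`, `r_squared`,
#'   `p_value`, `degenerate`, `significant`.  Skipped comparisons are
#'   listed in the `skipped` attribute.
#' @export
run_battery <- function(cohort, cfg = stats_config()) {
  if (isTRUE(cfg$exclude_confounded) &&
      all(c("smoker", "hypertensive") %in% names(cohort))) {
    cohort <- cohort[!(cohort$smoker | cohort$hypertensive), , drop = FALSE]
  }
  resp <- battery_responses()
  rows <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(resp))) {
    rcol <- paste0(resp$feature[i], "_", resp$site[i])
    rlabel <- paste0(toupper_feature(resp$feature[i]), "_", resp$site[i])
    for (pred in battery_predictors()) {
      pcol <- if (pred == "ipa") paste0("ipa_", resp$site[i]) else pred
      plabel <- if (pred == "ipa") paste0("IPA_", resp$site[i]) else pred
      if (!rcol %in% names(cohort) || !pcol %in% names(cohort)) {
        skipped <- c(skipped, sprintf("%s ~ %s: column missing", rlabel,
                                      plabel))
        next
      }
      ok <- is.finite(cohort[[rcol]]) & is.finite(cohort[[pcol]])
      if (sum(ok) < 3) {
        skipped <- c(skipped, sprintf("%s ~ %s: fewer than 3 complete rows",
                                      rlabel, plabel))
        next
      }
      cell <- linear_regression(cohort[[pcol]][ok], cohort[[rcol]][ok],
                                response = rlabel, predictor = plabel)
      cell$significant <- significance_gate(cell, cfg)
      rows[[length(rows) + 1L]] <- cell
    }
  }
  out <- tibble::as_tibble(do.call(rbind, rows))
  attr(out, "skipped") <- skipped
  out
}

toupper_feature <- function(x) {
  ifelse(x == "s2_over_s1", "S2/S1", toupper(x))
}

#' Sex comparison of height-normalized latencies
#'
#' Group means and SDs of height-normalized PAT and PTT (ms per meter) per
#' site, with the two-sample t-test for the male-female difference.
#'
#' @param cohort Cohort feature table.
#' @param cfg A [stats_config()].
#' @return Tibble with one row per site x latency: group summaries, `t`,
#'   `p_value`.
#' @export
sex_latency_summary <- function(cohort, cfg = stats_config()) {
  rows <- list()
  for (site in c("finger", "toe")) {
    for (feat in c("pat_norm", "ptt_norm")) {
      col <- paste0(feat, "_", site)
      if (!col %in% names(cohort)) next
      male <- cohort[[col]][cohort$sex_male == 1]
      female <- cohort[[col]][cohort$sex_male == 0]
      tt <- students_ttest(male, female, cfg)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        site = site, latency = feat,
        mean_male = tt$mean_a, sd_male = tt$sd_a, n_male = tt$n_a,
        mean_female = tt$mean_b, sd_female = tt$sd_b, n_female = tt$n_b,
        t = tt$t, p_value = tt$p_value)
    }
  }
  do.call(rbind, rows)
}

#' Render the battery as a text grid
#'
#' One row per response, one column per predictor; each cell shows
#' `r^2` and the p-value, with an asterisk when the dual gate passes.
#'
#' @param battery Result of [run_battery()].
#' @return Character vector of markdown table lines.
#' @export
format_battery_grid <- function(battery) {
  preds <- unique(battery$predictor)
  resps <- unique(battery$response)
  fmt_cell <- function(row) {
    if (!nrow(row)) return("--")
    if (isTRUE(row$degenerate)) return("degenerate")
    sprintf("r2=%.2f p=%.2g%s", row$r_squared, row$p_value,
            ifelse(row$significant, " *", ""))
  }
  header <- paste0("| response | ", paste(preds, collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", length(preds) + 1), collapse = "|"),
                "|")
  body <- vapply(resps, function(r) {
    cells <- vapply(preds, function(p) {
      fmt_cell(battery[battery$response == r & battery$predictor == p, ])
    }, character(1))
    paste0("| ", r, " | ", paste(cells, collapse = " | "), " |")
  }, character(1))
  c(header, sep, body)
}
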