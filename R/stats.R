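#' Bundled per-region RMS surface distances
#'
#' A transcription of the per-region RMS surface distances from a cadaveric
#' three-specimen comparative dataset: 18 circumscribed osteophyte regions
#' over five femoral knee sides, each scored against the structured-light
#' ground truth for both modality pairs (CT-SLS and 3DUS-SLS). Useful for
#' exercising the summary/statistics stage without running the geometric
#' pipeline.
#'
#' @param path optional path to a CSV of RMS records with columns
#'   `specimen,side,region_id,modality_pair,rms_mm`; defaults to the
#'   bundled dataset.
#' @return A tibble of RMS records.
#' @export
osteophyte_rms_example <- function(path = NULL) {
  path <- path %||% system.file("extdata", "osteophyte_rms.csv",
                                package = "osteorms", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen", "side", "region_id", "modality_pair", "rms_mm")
  if (!all(need %in% names(df))) {
    abort(sprintf("RMS record CSV must have columns: %s",
                  paste(need, collapse = ", ")))
  }
  as_tibble(df)
}

#' Summarise RMS records into mean/SD tables
#'
#' Arithmetic mean and sample standard deviation (n-1 denominator) of the
#' per-region RMS surface distances, either pooled over all regions or per
#' specimen-side group. Rounding happens only at presentation; the returned
#' values are unrounded.
#'
#' @param records tibble of RMS records with at least `modality_pair` and
#'   `rms_mm`; `specimen` and `side` are required for grouped summaries.
#' @param group_by `"overall"` (one row per modality pair) or
#'   `"specimen_side"`.
#' @return A tibble with columns `specimen`, `side` (for grouped output),
#'   `modality_pair`, `n`, `mean_mm`, `sd_mm`. `sd_mm` is `NA` for
#'   single-record groups (undefined).
#' @examples
#' records <- osteophyte_rms_example()
#' summarize_rms(records) # pooled means/SDs per modality pair
#' @export
summarize_rms <- function(records, group_by = c("overall", "specimen_side")) {
  group_by <- match.arg(group_by)
  if (!nrow(records)) abort("`records` is empty.")
  if (!all(c("modality_pair", "rms_mm") %in% names(records))) {
    abort("`records` must have columns `modality_pair` and `rms_mm`.")
  }
  keys <- if (group_by == "overall") "modality_pair" else
    c("specimen", "side", "modality_pair")
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_mm = mean(.data$rms_mm),
      sd_mm = ifelse(dplyr::n() >= 2, stats::sd(.data$rms_mm), NA_real_),
      .groups = "drop"
    )
}

#' Welch unequal-variance comparison of two error distributions
#'
#' Two-sample t test without the equal-variance assumption (Welch), with
#' Welch-Satterthwaite degrees of freedom and a two-tailed p value; the
#' default test for comparing per-region RMS distances between modality
#' pairs. A paired variant is available via `paired = TRUE`, but note that
#' with per-region error values the Welch form is the one whose p values
#' match the published within-specimen comparison.
#'
#' @param group_a,group_b numeric vectors of RMS values (mm), each of
#'   length >= 2.
#' @param paired use the paired t test instead of Welch's.
#' @return An object of class `welch_result` with elements `t`, `df`, `p`,
#'   `mean_a`, `mean_b`, `n_a`, `n_b`, `method`.
#' @examples
#' ct <- c(1.30, 1.30, 1.37, 1.03)
#' us <- c(0.56, 0.51, 0.61, 0.83)
#' welch_test(ct, us) # p ~ 0.001
#' @export
welch_test <- function(group_a, group_b, paired = FALSE) {
  group_a <- as.numeric(group_a)
  group_b <- as.numeric(group_b)
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("Each group needs at least 2 values.")
  }
  if (!all(is.finite(group_a)) || !all(is.finite(group_b))) {
    abort("Groups must contain finite values only.")
  }
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    # degenerate: no variance anywhere
    equal <- isTRUE(all.equal(mean(group_a), mean(group_b)))
    ht <- list(statistic = c(t = if (equal) 0 else Inf),
               parameter = c(df = length(group_a) + length(group_b) - 2),
               p.value = if (equal) 1 else 0)
  } else {
    ht <- stats::t.test(group_a, group_b, paired = paired, var.equal = FALSE)
  }
  structure(
    list(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value, mean_a = mean(group_a), mean_b = mean(group_b),
         n_a = length(group_a), n_b = length(group_b),
         method = if (paired) "paired t" else "Welch"),
    class = "welch_result"
  )
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("<welch_result> %s test: t = %.3f, df = %.2f, p = %.4g\n",
              x$method, x$t, x$df, x$p))
  invisible(x)
}

#' @export
tidy.welch_result <- function(x, ...) {
  tibble(method = x$method, t = x$t, df = x$df, p_value = x$p,
         mean_a = x$mean_a, mean_b = x$mean_b, n_a = x$n_a, n_b = x$n_b)
}

#' @export
glance.welch_result <- function(x, ...) tidy(x)

#' Full modality-comparison report
#'
#' Assembles the analysis tables from a set of per-region RMS records:
#' pooled and per-specimen-side mean/SD summaries, plus a Welch comparison
#' of CT-SLS against 3DUS-SLS errors overall and within each specimen-side
#' that has at least two regions, flagged for significance at `alpha`.
#'
#' @param records tibble of RMS records (both modality pairs present).
#' @param alpha significance level for flags (default 0.05).
#' @param paired also run the paired variant alongside Welch.
#' @return An object of class `modality_comparison`: list with `summary`
#'   (per-group tibble in wide form), `overall` (pooled tibble), `tests`
#'   (tibble of test results with `significant` flags) and `alpha`.
#' @examples
#' rep <- compare_report(osteophyte_rms_example())
#' rep$tests
#' @export
compare_report <- function(records, alpha = 0.05, paired = FALSE) {
  pairs <- unique(records$modality_pair)
  if (length(pairs) < 2) {
    abort("`records` must contain both modality pairs (found only one).")
  }
  if (length(pairs) != 2) {
    abort(sprintf("Expected exactly 2 modality pairs, found: %s",
                  paste(pairs, collapse = ", ")))
  }
  overall <- summarize_rms(records, "overall")
  by_group <- summarize_rms(records, "specimen_side")

  run_test <- function(df) {
    a <- df$rms_mm[df$modality_pair == pairs[1]]
    b <- df$rms_mm[df$modality_pair == pairs[2]]
    if (length(a) < 2 || length(b) < 2) return(NULL)
    wt <- welch_test(a, b, paired = paired && length(a) == length(b))
    tidy(wt)
  }
  tests <- records |>
    dplyr::group_by(.data$specimen, .data$side) |>
    dplyr::group_modify(~ run_test(.x) %||% tibble()) |>
    dplyr::ungroup()
  ov <- run_test(records) |>
    dplyr::mutate(specimen = "ALL", side = "ALL", .before = 1)
  tests <- dplyr::bind_rows(tests, ov) |>
    dplyr::mutate(
      comparison = paste(pairs[1], "vs", pairs[2]),
      significant = .data$p_value <= alpha
    )
  wide <- by_group |>
    tidyr::pivot_wider(names_from = "modality_pair",
                       values_from = c("n", "mean_mm", "sd_mm"))
  structure(
    list(summary = wide, by_group = by_group, overall = overall,
         tests = tests, alpha = alpha),
    class = "modality_comparison"
  )
}

#' @export
print.modality_comparison <- function(x, ...) {
  cat("<modality_comparison>\n\nPooled RMS surface distance (mm):\n")
  print(as.data.frame(x$overall), digits = 3)
  cat("\nPer specimen-side:\n")
  print(as.data.frame(x$by_group), digits = 3)
  cat(sprintf("\nWelch comparisons (alpha = %.2f):\n", x$alpha))
  print(as.data.frame(x$tests[, c("specimen", "side", "t", "df", "p_value",
                                  "significant")]), digits = 3)
  invisible(x)
}

#' @export
tidy.modality_comparison <- function(x, ...) x$tests

#' @export
glance.modality_comparison <- function(x, ...) {
  ov <- x$tests[x$tests$specimen == "ALL", ]
  tibble(
    n_regions = sum(x$overall$n) / nrow(x$overall),
    alpha = x$alpha,
    overall_t = ov$t, overall_df = ov$df, overall_p = ov$p_value,
    overall_significant = ov$significant
  )
}

#' Write a comparison report to disk
#'
#' Emits `summary.csv` (per-group means/SDs in wide form) and `tests.json`
#' (all Welch results with significance flags).
#'
#' @param report a `modality_comparison`.
#' @param dir output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_comparison <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report$tests, file.path(dir, "tests.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
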