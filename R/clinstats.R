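# Correlations between regional z-VMHC sphere means and clinical scores
# (PANSS subscales/total across patients, AHRS in AVH patients), with
# two-tailed t-based p values.

#' Two-tailed p value for a Pearson correlation
#'
#' `p = 2 (1 - T_{n-2}(|r| sqrt(n-2) / sqrt(1-r^2)))` with `T` the central-t
#' CDF: symmetric in the sign of r, decreasing in |r| at fixed n and in n at
#' fixed nonzero r.
#'
#' @param r Pearson correlation, |r| <= 1.
#' @param n number of paired observations (>= 3).
#' @return Two-tailed p value. `|r| = 1` returns 0 with a degeneracy warning.
#' @export
p_from_r <- function(r, n) {
  stopifnot(abs(r) <= 1, n >= 3)
  if (abs(r) == 1) {
    warning("|r| = 1 is degenerate; returning p = 0")
    return(0)
  }
  tval <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(abs(tval), n - 2, lower.tail = FALSE)
}

#' Pearson correlation with t-based inference
#'
#' Sample Pearson r with `t = r sqrt(n-2) / sqrt(1-r^2)` and its two-tailed p
#' from the t distribution with n - 2 df. Pairs with a missing member are
#' dropped (pairwise deletion).
#'
#' @param x,y paired numeric vectors.
#' @param x_name,y_name labels used in error messages and output.
#' @return One-row tibble: `r`, `n`, `t_stat`, `p_two_tailed`.
#' @export
pearson_r <- function(x, y, x_name = "x", y_name = "y") {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs, got ", n)
  if (stats::sd(x) == 0) stop("zero variance in '", x_name, "'")
  if (stats::sd(y) == 0) stop("zero variance in '", y_name, "'")
  r <- stats::cor(x, y)
  tval <- r * sqrt(n - 2) / sqrt(1 - r^2)
  tibble::tibble(r = r, n = n, t_stat = tval,
                 p_two_tailed = p_from_r(r, n))
}

#' Score-connectivity correlation table
#'
#' Pearson correlations between every clinical score and every region's
#' sphere-mean z-VMHC over the selected cohort, with pairwise-complete
#' observations. No multiple-comparison correction is applied by default;
#' `adjust = TRUE` adds Benjamini-Hochberg adjusted p values.
#'
#' @param sphere_means tibble with `subject_id` and one column per region
#'   (from [sphere_means_table()]).
#' @param records subject tibble with `subject_id`, `group`, and score
#'   columns.
#' @param cohort `"all_patients"` (AVH + NonAVH), `"avh_only"`, or
#'   `"nonavh_only"`.
#' @param scores score columns to use; defaults to the PANSS subscales/total
#'   for patient cohorts plus AHRS for the AVH cohort.
#' @param adjust add BH-adjusted p values?
#' @return Long tibble: `region`, `score`, `cohort`, `r`, `n`, `t_stat`,
#'   `p_two_tailed` (and `p_adjusted` when requested).
#' @export
correlation_table <- function(sphere_means, records,
                              cohort = c("all_patients", "avh_only",
                                         "nonavh_only"),
                              scores = NULL, adjust = FALSE) {
  cohort <- match.arg(cohort)
  keep_groups <- switch(cohort,
                        all_patients = c("AVH", "NonAVH"),
                        avh_only = "AVH",
                        nonavh_only = "NonAVH")
  if (is.null(scores)) {
    scores <- c("panss_pos", "panss_neg", "panss_gen", "panss_total")
    if (cohort == "avh_only") scores <- c(scores, "ahrs")
    scores <- intersect(scores, names(records))
  }
  regions <- setdiff(names(sphere_means), "subject_id")
  if (length(regions) == 0) stop("sphere_means contains no region columns")
  df <- dplyr::inner_join(dplyr::filter(records, .data$group %in% keep_groups),
                          sphere_means, by = "subject_id")
  if (nrow(df) == 0) stop("cohort '", cohort, "' is empty")
  out <- list()
  for (reg in regions) {
    for (sc in scores) {
      if (!sc %in% names(df)) stop("score '", sc, "' absent from records")
      row <- pearson_r(df[[sc]], df[[reg]], x_name = sc, y_name = reg)
      out[[length(out) + 1]] <- dplyr::bind_cols(
        tibble::tibble(region = reg, score = sc, cohort = cohort), row)
    }
  }
  res <- dplyr::bind_rows(out)
  if (adjust) res$p_adjusted <- stats::p.adjust(res$p_two_tailed, "BH")
  res
}

#' Serialize a correlation table in the alternating r/p layout
#'
#' Writes a wide TSV with one column per score and, per region, an `r` row
#' followed by a `p` row (values rounded to two decimals only here, never in
#' computation), plus a long-format TSV with full precision.
#'
#' @param tab output of [correlation_table()].
#' @param path_wide,path_long output file paths (`NULL` to skip either).
#' @return The wide-format data frame, invisibly.
#' @export
write_correlation_tsv <- function(tab, path_wide = NULL, path_long = NULL) {
  scores <- unique(tab$score)
  rows <- list()
  for (reg in unique(tab$region)) {
    sub <- tab[tab$region == reg, ]
    r_row <- c(region = reg, stat = "r",
               stats::setNames(sprintf("%.2f", sub$r[match(scores, sub$score)]),
                               scores))
    p_row <- c(region = "", stat = "p",
               stats::setNames(sprintf("%.2f",
                                       sub$p_two_tailed[match(scores, sub$score)]),
                               scores))
    rows[[length(rows) + 1]] <- r_row
    rows[[length(rows) + 1]] <- p_row
  }
  wide <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  if (!is.null(path_wide)) {
    utils::write.table(wide, path_wide, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(path_long)) {
    utils::write.table(tab, path_long, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(wide)
}
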