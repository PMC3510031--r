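#' Paired fold-change (waterfall) analysis of terminal modification
#'
#' For each miRNA passing the wild-type filters, computes the per-pair
#' ratio of percent modified in the knockout over percent modified in the
#' wild type, combines pairs by geometric mean, and summarises across
#' miRNAs with a one-sample t-test of the log2 fold-changes against 0 and
#' a 95% confidence interval (t distribution, df = n - 1).
#'
#' Inclusion requires the summed wild-type reads across libraries to exceed
#' `min_reads` and the pooled (read-weighted) wild-type modified percent to
#' exceed `min_pct`; both filters are strict, and miRNAs with an undefined
#' percent in any library are excluded with reason `"missing_data"`. When a
#' pair's percent is zero on either side, half the minimum detectable
#' percent in that library (100 x 0.5 / total reads) is added to both
#' numerator and denominator so the geometric mean stays defined.
#'
#' @param profiles Profile tibble from [build_profiles()].
#' @param manifest Manifest tibble with `library_id`, `genotype`, `pair_id`.
#' @param nucleotide `"U"` or `"A"`.
#' @param min_reads Wild-type summed read filter (default 10000).
#' @param min_pct Wild-type pooled percent-modified filter (default 0.1).
#' @return An object of class `waterfall_fit` with elements `table` (per
#'   miRNA: per-pair ratios, geometric-mean ratio, log2 fold-change,
#'   inclusion flag and reason), `summary` (mean log2 fold-change, 95% CI,
#'   t statistic, p-value, n) and `params`.
#' @export
waterfall <- function(profiles, manifest, nucleotide = c("U", "A"),
                      min_reads = 10000, min_pct = 0.1) {
  nucleotide <- match.arg(nucleotide)
  pct_col <- if (nucleotide == "U") "pct_uridylated" else "pct_adenylated"
  pairs <- manifest %>% distinct(.data$pair_id, .data$genotype,
                                 .data$library_id)
  if (nrow(pairs %>% distinct(.data$pair_id)) < 2L) {
    abort("waterfall requires at least 2 WT/KO pairs")
  }
  p <- join_genotype(profiles, manifest) %>%
    select("mirna_name", "library_id", "genotype", "pair_id",
           "total_reads", pct = dplyr::all_of(pct_col))

  wt_filters <- p %>%
    filter(.data$genotype == "WT") %>%
    group_by(.data$mirna_name) %>%
    summarise(
      wt_reads = sum(.data$total_reads),
      wt_pooled_pct = if (sum(.data$total_reads) > 0) {
        100 * sum(.data$pct * .data$total_reads / 100, na.rm = TRUE) /
          sum(.data$total_reads)
      } else NA_real_,
      .groups = "drop")

  wide <- p %>%
    tidyr::pivot_wider(id_cols = c("mirna_name", "pair_id"),
                       names_from = "genotype",
                       values_from = c("pct", "total_reads"))
  ratios <- wide %>%
    mutate(
      pc_wt = 100 * 0.5 / pmax(.data$total_reads_WT, 1L),
      pc_ko = 100 * 0.5 / pmax(.data$total_reads_KO, 1L),
      use_pc = !is.na(.data$pct_WT) & !is.na(.data$pct_KO) &
        (.data$pct_WT == 0 | .data$pct_KO == 0),
      ratio = dplyr::if_else(
        .data$use_pc,
        (.data$pct_KO + .data$pc_ko) / (.data$pct_WT + .data$pc_wt),
        .data$pct_KO / .data$pct_WT))

  per_mirna <- ratios %>%
    group_by(.data$mirna_name) %>%
    summarise(ratios = list(stats::setNames(.data$ratio,
                                            .data$pair_id)),
              n_pairs = dplyr::n(),
              any_missing = any(is.na(.data$ratio)),
              geomean_ratio = exp(mean(log(.data$ratio))),
              .groups = "drop") %>%
    left_join(wt_filters, by = "mirna_name") %>%
    mutate(
      exclusion_reason = dplyr::case_when(
        .data$any_missing ~ "missing_data",
        .data$wt_reads <= min_reads ~ "min_reads",
        is.na(.data$wt_pooled_pct) | .data$wt_pooled_pct <= min_pct ~
          "min_pct",
        TRUE ~ NA_character_),
      included = is.na(.data$exclusion_reason),
      geomean_ratio = dplyr::if_else(.data$any_missing, NA_real_,
                                     .data$geomean_ratio),
      log2_fc = log2(.data$geomean_ratio),
      nucleotide = nucleotide) %>%
    select("mirna_name", "nucleotide", "ratios", "n_pairs", "wt_reads",
           "wt_pooled_pct", "geomean_ratio", "log2_fc", "included",
           "exclusion_reason")

  x <- per_mirna$log2_fc[per_mirna$included]
  if (length(x) == 0L) {
    warn(paste0("no miRNA passes the waterfall filters (nucleotide ",
                nucleotide, ")"))
    summary_tbl <- tibble(nucleotide = nucleotide, n_mirnas = 0L,
                          mean_log2_fc = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, statistic = NA_real_,
                          p_value = NA_real_)
  } else if (length(x) == 1L || sd(x) == 0) {
    summary_tbl <- tibble(nucleotide = nucleotide, n_mirnas = length(x),
                          mean_log2_fc = mean(x), ci_low = mean(x),
                          ci_high = mean(x),
                          statistic = if (all(x == 0)) 0 else NA_real_,
                          p_value = if (all(x == 0)) 1 else NA_real_)
  } else {
    ht <- t.test(x, mu = 0)
    summary_tbl <- tibble(nucleotide = nucleotide, n_mirnas = length(x),
                          mean_log2_fc = unname(ht$estimate),
                          ci_low = ht$conf.int[1], ci_high = ht$conf.int[2],
                          statistic = unname(ht$statistic),
                          p_value = ht$p.value)
  }
  structure(list(table = per_mirna, summary = summary_tbl,
                 params = list(nucleotide = nucleotide,
                               min_reads = min_reads, min_pct = min_pct)),
            class = "waterfall_fit")
}

#' @export
print.waterfall_fit <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Waterfall fold-change analysis (%s additions)\n",
              s$nucleotide))
  cat(sprintf("  miRNAs included: %d (of %d)\n", s$n_mirnas,
              nrow(x$table)))
  if (!is.na(s$mean_log2_fc)) {
    cat(sprintf("  mean log2 KO/WT fold-change: %.3f [%.3f, %.3f]\n",
                s$mean_log2_fc, s$ci_low, s$ci_high))
    cat(sprintf("  t = %.3f, p = %.3g (one-sample vs 0)\n",
                s$statistic, s$p_value))
  }
  invisible(x)
}

#' Tidy a waterfall fit
#'
#' @param x A `waterfall_fit`.
#' @param ... Unused.
#' @return The per-miRNA table (one row per miRNA with the geometric-mean
#'   KO/WT ratio, log2 fold-change and inclusion status).
#' @export
tidy.waterfall_fit <- function(x, ...) {
  x$table
}

#' One-row summary of a waterfall fit
#'
#' @param x A `waterfall_fit`.
#' @param ... Unused.
#' @return The summary tibble (mean log2 fold-change, 95% CI, t, p, n).
#' @export
glance.waterfall_fit <- function(x, ...) {
  x$summary
}

#' Waterfall bar plot of per-miRNA fold-changes
#'
#' @param object A `waterfall_fit`.
#' @param ... Unused.
#' @return A ggplot: included miRNAs sorted by log2 fold-change.
#' @export
autoplot.waterfall_fit <- function(object, ...) {
  d <- object$table %>%
    filter(.data$included) %>%
    arrange(dplyr::desc(.data$log2_fc)) %>%
    mutate(rank = dplyr::row_number())
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$log2_fc)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(
      x = "miRNA (ranked)",
      y = "log2 geometric-mean KO/WT percent modified",
      title = sprintf("Terminal %s additions", object$summary$nucleotide)) +
    ggplot2::theme_minimal()
}

#' Read-length histogram plot
#'
#' @param object A `length_histogram`.
#' @param ... Unused.
#' @return A ggplot of per-library length fractions by genotype.
#' @export
autoplot.length_histogram <- function(object, ...) {
  d <- object$histogram %>%
    group_by(.data$genotype, .data$length) %>%
    summarise(mean_fraction = mean(.data$fraction),
              se = sd(.data$fraction) / sqrt(dplyr::n()),
              .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$length, y = .data$mean_fraction,
                                  fill = .data$genotype)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_fraction - .data$se,
                   ymax = .data$mean_fraction + .data$se),
      position = ggplot2::position_dodge(width = 0.9), width = 0.3) +
    ggplot2::labs(x = "read length (nt)", y = "fraction of reads") +
    ggplot2::theme_minimal()
}

#' Log-log RPM scatter of mean WT vs KO abundance
#'
#' @param rpm Output of [quantify_rpm()].
#' @param manifest Manifest with `library_id`, `genotype`.
#' @param offset Pseudo-RPM added before the log.
#' @return A ggplot.
#' @export
plot_rpm_scatter <- function(rpm, manifest, offset = 1) {
  d <- join_genotype(rpm, manifest) %>%
    group_by(.data$mirna_name, .data$genotype) %>%
    summarise(mean_rpm = mean(.data$rpm), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "genotype", values_from = "mean_rpm")
  ggplot2::ggplot(d, ggplot2::aes(x = log10(.data$WT + offset),
                                  y = log10(.data$KO + offset))) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "log10 mean WT RPM", y = "log10 mean KO RPM") +
    ggplot2::theme_minimal()
}
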