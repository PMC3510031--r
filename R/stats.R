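#' Reads-per-million quantification
#'
#' RPM = 1e6 x reads / total aligned miRNA reads in the library, so each
#' library's RPM column sums to one million.
#'
#' @param x Either a profile tibble from [build_profiles()] (uses
#'   `total_reads`) or an alignment tibble with `mirna_name` and
#'   `library_id` columns (reads are counted).
#' @return Tibble `library_id`, `mirna_name`, `reads`, `rpm`.
#' @export
quantify_rpm <- function(x) {
  counts <- if ("total_reads" %in% names(x)) {
    x %>% select("library_id", "mirna_name", reads = "total_reads")
  } else {
    x %>% count(.data$library_id, .data$mirna_name, name = "reads")
  }
  counts <- counts %>%
    group_by(.data$library_id) %>%
    mutate(lib_total = sum(.data$reads)) %>%
    ungroup()
  if (any(counts$lib_total == 0)) {
    bad <- unique(counts$library_id[counts$lib_total == 0])
    abort(paste0("library with zero aligned reads: ", bad[1]))
  }
  counts %>%
    mutate(rpm = 1e6 * .data$reads / .data$lib_total) %>%
    select("library_id", "mirna_name", "reads", "rpm")
}

join_genotype <- function(x, manifest) {
  left_join(x, manifest %>% select("library_id", "genotype", "pair_id"),
            by = "library_id")
}

#' Between-genotype correlation of miRNA abundance
#'
#' Pearson correlation between mean WT and mean KO RPM per miRNA,
#' restricted to miRNAs detected (>= 1 read) in at least one library of
#' each genotype. Computed on `log10(RPM + offset)` by default since
#' abundances span orders of magnitude.
#'
#' @param rpm Output of [quantify_rpm()].
#' @param manifest Manifest tibble with `library_id`, `genotype`.
#' @param scale `"log10"` (default) or `"linear"`.
#' @param offset Pseudo-RPM added before the log.
#' @return One-row tibble: `r`, `n_mirnas`, `scale`.
#' @export
genotype_correlation <- function(rpm, manifest, scale = c("log10", "linear"),
                                 offset = 1) {
  scale <- match.arg(scale)
  wide <- join_genotype(rpm, manifest) %>%
    group_by(.data$mirna_name, .data$genotype) %>%
    summarise(mean_rpm = mean(.data$rpm), detected = any(.data$reads > 0),
              .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "genotype",
                       values_from = c("mean_rpm", "detected"))
  wide <- wide %>%
    filter(.data$detected_WT %in% TRUE | .data$detected_KO %in% TRUE) %>%
    filter(!is.na(.data$mean_rpm_WT), !is.na(.data$mean_rpm_KO))
  if (nrow(wide) < 3L) {
    abort("fewer than 3 miRNAs detected in both genotypes")
  }
  x <- wide$mean_rpm_WT
  y <- wide$mean_rpm_KO
  if (scale == "log10") {
    x <- log10(x + offset)
    y <- log10(y + offset)
  }
  tibble(r = cor(x, y), n_mirnas = nrow(wide), scale = scale)
}

#' Read-length histogram with genotype testing
#'
#' Builds per-library read-length fractions over `lengths` and, when both
#' genotypes have at least two libraries, fits a two-way fixed-effects
#' ANOVA (genotype x length) on the fractions and tests the per-length
#' genotype contrast using the ANOVA residual variance, Bonferroni-adjusted
#' across the number of lengths tested.
#'
#' @param read_lengths Tibble with `library_id` and `length` (trimmed
#'   insert lengths in nt).
#' @param manifest Manifest tibble with `library_id`, `genotype`.
#' @param lengths Integer vector of length bins (default 15-30 nt).
#' @return A list of class `length_histogram`: `histogram` (per-library
#'   counts and fractions), `anova` (tidy ANOVA table or `NULL`),
#'   `contrasts` (per-length difference WT - KO, t statistic, raw and
#'   Bonferroni-adjusted p) and `tested`.
#' @export
length_histogram_test <- function(read_lengths, manifest,
                                  lengths = 15:30) {
  hist <- tidyr::crossing(library_id = unique(manifest$library_id),
                          length = as.integer(lengths)) %>%
    left_join(read_lengths %>%
                filter(.data$length %in% lengths) %>%
                count(.data$library_id, .data$length, name = "count"),
              by = c("library_id", "length")) %>%
    mutate(count = dplyr::coalesce(.data$count, 0L)) %>%
    group_by(.data$library_id) %>%
    mutate(fraction = .data$count / sum(.data$count)) %>%
    ungroup() %>%
    join_genotype(manifest)

  n_per_geno <- manifest %>% count(.data$genotype)
  tested <- nrow(n_per_geno) == 2L && all(n_per_geno$n >= 2L)
  anova_tbl <- NULL
  contrasts <- NULL
  if (!tested) {
    warn("a genotype has fewer than 2 libraries; ANOVA skipped")
  } else {
    d <- hist %>%
      mutate(genotype = factor(.data$genotype, levels = c("WT", "KO")),
             length_f = factor(.data$length))
    fit <- aov(fraction ~ genotype * length_f, data = d)
    sm <- summary(fit)[[1]]
    anova_tbl <- tibble(term = trimws(rownames(sm)),
                        df = sm$Df, sumsq = sm$`Sum Sq`,
                        meansq = sm$`Mean Sq`, statistic = sm$`F value`,
                        p_value = sm$`Pr(>F)`)
    ms_res <- anova_tbl$meansq[anova_tbl$term == "Residuals"]
    df_res <- anova_tbl$df[anova_tbl$term == "Residuals"]
    n_wt <- n_per_geno$n[n_per_geno$genotype == "WT"]
    n_ko <- n_per_geno$n[n_per_geno$genotype == "KO"]
    contrasts <- d %>%
      group_by(.data$length) %>%
      summarise(
        mean_wt = mean(.data$fraction[.data$genotype == "WT"]),
        mean_ko = mean(.data$fraction[.data$genotype == "KO"]),
        .groups = "drop") %>%
      mutate(
        diff = .data$mean_wt - .data$mean_ko,
        statistic = .data$diff / sqrt(ms_res * (1 / n_wt + 1 / n_ko)),
        p_raw = 2 * stats::pt(abs(.data$statistic), df_res,
                              lower.tail = FALSE),
        p_adj = pmin(1, .data$p_raw * length(lengths)))
  }
  structure(list(histogram = hist, anova = anova_tbl,
                 contrasts = contrasts, tested = tested,
                 lengths = as.integer(lengths)),
            class = "length_histogram")
}

#' Chi-squared goodness-of-fit test
#'
#' @param observed Integer vector of category counts.
#' @param expected_props Expected proportions (must sum to 1, all positive).
#' @return One-row tibble: `statistic` (X² = sum (obs - exp)²/exp), `df`
#'   (categories - 1) and `p_value` (upper tail).
#' @export
chisq_gof <- function(observed, expected_props) {
  if (length(observed) != length(expected_props)) {
    abort("observed and expected_props must have equal length")
  }
  if (abs(sum(expected_props) - 1) > 1e-8) {
    abort("expected_props must sum to 1")
  }
  if (any(expected_props <= 0)) abort("expected proportions must be > 0")
  ht <- stats::chisq.test(x = observed, p = expected_props)
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = unname(ht$p.value))
}

#' Count species with consistent unambiguous uridylation per genotype
#'
#' Restricts to miRNAs with at least one read in every library of both
#' genotypes, then counts the species whose unambiguous-uridylation count
#' meets `min_events` in every WT library (`n_wt`) and analogously for KO
#' (`n_ko`), and tests the two counts. The default test is a 2-category
#' goodness of fit of `(n_wt, n_ko)` against equal proportions; the
#' `"contingency"` option instead tests a 2 x 2 table of
#' with/without-event species per genotype over the shared universe.
#'
#' @param profiles Profile tibble from [build_profiles()].
#' @param manifest Manifest tibble with `library_id`, `genotype`.
#' @param min_events Events per library needed to call a species uridylated
#'   (default 1 NQS-passing read).
#' @param test `"gof"` (default) or `"contingency"`.
#' @return A list of class `species_counts`: `n_wt`, `n_ko`,
#'   `universe_size`, `test` (tibble), `min_events`.
#' @export
species_uridylation_counts <- function(profiles, manifest, min_events = 1L,
                                       test = c("gof", "contingency")) {
  test <- match.arg(test)
  p <- join_genotype(profiles, manifest)
  per_species <- p %>%
    group_by(.data$mirna_name) %>%
    summarise(
      in_all = all(.data$total_reads >= 1L),
      wt_all = all(.data$unambiguous_U_count[.data$genotype == "WT"] >=
                     min_events),
      ko_all = all(.data$unambiguous_U_count[.data$genotype == "KO"] >=
                     min_events),
      .groups = "drop") %>%
    filter(.data$in_all)
  if (nrow(per_species) == 0L) {
    abort("no miRNA observed in every library of both genotypes")
  }
  n_wt <- sum(per_species$wt_all)
  n_ko <- sum(per_species$ko_all)
  ht <- if (test == "gof") {
    chisq_gof(c(n_wt, n_ko), c(0.5, 0.5))
  } else {
    m <- rbind(c(n_wt, nrow(per_species) - n_wt),
               c(n_ko, nrow(per_species) - n_ko))
    t0 <- stats::chisq.test(m, correct = FALSE)
    tibble(statistic = unname(t0$statistic), df = unname(t0$parameter),
           p_value = unname(t0$p.value))
  }
  structure(list(n_wt = n_wt, n_ko = n_ko,
                 universe_size = nrow(per_species),
                 test = ht, test_type = test, min_events = min_events),
            class = "species_counts")
}

#' @export
print.species_counts <- function(x, ...) {
  cat("Species with unambiguous uridylation in every library\n")
  cat(sprintf("  shared miRNA universe: %d\n", x$universe_size))
  cat(sprintf("  WT: %d   KO: %d\n", x$n_wt, x$n_ko))
  cat(sprintf("  chi-squared (%s) = %.3f, df = %d, p = %.3g\n",
              x$test_type, x$test$statistic, x$test$df, x$test$p_value))
  invisible(x)
}
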