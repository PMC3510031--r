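#' Neighborhood quality score (NQS) parameters
#'
#' The NQS filter accepts a base call iff the call-site quality meets a
#' minimum and the mean quality over a centered window (truncated at read
#' ends) meets a second minimum.
#'
#' @param min_central_quality Minimum Phred score at the call site.
#' @param min_window_mean_quality Minimum mean Phred score over the window.
#' @param window_length Odd window width in bases (call site at center).
#' @return A list of class `nqs_params`.
#' @export
nqs_params <- function(min_central_quality = 20,
                       min_window_mean_quality = 15,
                       window_length = 5L) {
  window_length <- as.integer(window_length)
  if (window_length < 1L || window_length %% 2L == 0L) {
    abort("window_length must be odd and >= 1")
  }
  if (min_central_quality < 0 || min_window_mean_quality < 0) {
    abort("quality thresholds must be >= 0")
  }
  structure(list(min_central_quality = min_central_quality,
                 min_window_mean_quality = min_window_mean_quality,
                 window_length = window_length),
            class = "nqs_params")
}

#' Does a base call pass the NQS filter?
#'
#' @param qualities Integer Phred scores for one read (or a Phred+33
#'   string).
#' @param center_index 1-based position of the call site within the read.
#' @param params An [nqs_params()].
#' @return `TRUE` iff the call site meets `min_central_quality` and the
#'   mean over the `window_length` window centered there (truncated at read
#'   ends) meets `min_window_mean_quality`.
#' @export
nqs_pass <- function(qualities, center_index, params = nqs_params()) {
  if (is.character(qualities)) qualities <- phred_scores(qualities)[[1]]
  n <- length(qualities)
  if (center_index < 1L || center_index > n) {
    abort("center_index out of range")
  }
  half <- (params$window_length - 1L) %/% 2L
  win <- qualities[max(1L, center_index - half):min(n, center_index + half)]
  qualities[center_index] >= params$min_central_quality &&
    mean(win) >= params$min_window_mean_quality
}

# Vectorised NQS over rows: quality strings, 1-based centers.
nqs_pass_at <- function(qualities, centers, params) {
  if (length(qualities) == 0L) return(logical(0))
  half <- (params$window_length - 1L) %/% 2L
  len <- nchar(qualities)
  central <- phred_at(qualities, centers)
  winmean <- phred_window_mean(qualities, pmax(1L, centers - half),
                               pmin(len, centers + half))
  !is.na(central) & central >= params$min_central_quality &
    winmean >= params$min_window_mean_quality
}

# Frequency comparator for retained variants ("ge": >= threshold, the
# reported analysis; "gt": strictly >).
freq_keep <- function(count, total, min_freq, comparator) {
  frac <- ifelse(total > 0, count / total, 0)
  if (comparator == "ge") frac >= min_freq else frac > min_freq
}

# Per-(mature sequence, offset) templated-T lookup covering multi-locus
# miRNAs: TRUE iff ANY catalog entry sharing the mature sequence has T at
# that flank offset.
flank_t_lookup <- function(catalog, max_offset = 5L) {
  purrr::map_dfr(seq_len(max_offset), function(k) {
    catalog %>%
      group_by(.data$mature_seq) %>%
      summarise(offset = k,
                any_T = any(substr(.data$flank3, k, k) == "T"),
                .groups = "drop")
  })
}

# Core per-(miRNA, library) profile computation over an alignment table.
profile_engine <- function(alignments, catalog, params, min_variant_freq,
                           comparator, libraries = NULL) {
  al <- alignments
  if (!"library_id" %in% names(al)) al$library_id <- "library"
  if (is.null(libraries)) libraries <- unique(al$library_id)

  totals <- al %>%
    count(.data$mirna_name, .data$library_id, name = "total_reads")

  # +1 tabulation: unambiguous assignments with a positive overhang whose
  # +1 base passes NQS
  tails <- al %>%
    filter(!.data$ambiguous, .data$terminal_read_offset >= 1L) %>%
    mutate(plus1_base = substr(.data$overhang_seq, 1L, 1L),
           plus1_pos = .data$read_len - .data$terminal_read_offset + 1L)
  if (nrow(tails) > 0L) {
    tails$nqs_ok <- nqs_pass_at(tails$qualities, tails$plus1_pos, params)
  } else {
    tails$nqs_ok <- logical(0)
  }
  plus1 <- tails %>%
    filter(.data$nqs_ok, .data$plus1_base %in% c("A", "C", "G", "T")) %>%
    count(.data$mirna_name, .data$library_id, .data$plus1_base) %>%
    tidyr::pivot_wider(names_from = "plus1_base", values_from = "n",
                       names_prefix = "plus1_", values_fill = 0L)

  tail_lens <- tails %>%
    filter(.data$terminal_read_offset <= 5L) %>%
    count(.data$mirna_name, .data$library_id, .data$terminal_read_offset) %>%
    tidyr::pivot_wider(names_from = "terminal_read_offset",
                       values_from = "n", names_prefix = "tail_",
                       values_fill = 0L)

  # unambiguous uridylation: terminal T over a non-T template at the
  # read's terminal position (mature body when the read does not extend
  # past the terminus, genomic flank when it does; for shared mature
  # sequences every entry's flank must be non-T)
  cat_seq <- catalog %>% select("name", "mature_seq")
  term <- al %>%
    filter(!.data$ambiguous, .data$terminal_read_base == "T",
           .data$terminal_read_offset <= 5L) %>%
    left_join(cat_seq, by = c(mirna_name = "name"))
  if (nrow(term) > 0L) {
    lk <- flank_t_lookup(catalog)
    term <- term %>%
      left_join(lk, by = c("mature_seq", terminal_read_offset = "offset")) %>%
      mutate(templated_T = dplyr::if_else(
        .data$terminal_read_offset <= 0L,
        substr(.data$mature_seq, .data$read_len, .data$read_len) == "T",
        .data$any_T %in% TRUE)) %>%
      filter(!.data$templated_T)
    term$nqs_ok <- nqs_pass_at(term$qualities, term$read_len, params)
    unamb <- term %>%
      filter(.data$nqs_ok) %>%
      count(.data$mirna_name, .data$library_id,
            name = "unambiguous_U_count")
  } else {
    unamb <- tibble(mirna_name = character(0), library_id = character(0),
                    unambiguous_U_count = integer(0))
  }

  grid <- tidyr::crossing(mirna_name = catalog$name, library_id = libraries)
  out <- grid %>%
    left_join(totals, by = c("mirna_name", "library_id")) %>%
    left_join(plus1, by = c("mirna_name", "library_id")) %>%
    left_join(tail_lens, by = c("mirna_name", "library_id")) %>%
    left_join(unamb, by = c("mirna_name", "library_id"))
  for (col in c("total_reads", paste0("plus1_", c("A", "C", "G", "T")),
                paste0("tail_", 1:5), "unambiguous_U_count")) {
    if (!col %in% names(out)) out[[col]] <- 0L
    out[[col]][is.na(out[[col]])] <- 0L
  }
  templated1 <- catalog %>%
    mutate(templated_plus1 = substr(.data$flank3, 1L, 1L)) %>%
    select(mirna_name = "name", "templated_plus1")
  out <- out %>%
    left_join(templated1, by = "mirna_name") %>%
    mutate(
      defined = .data$total_reads > 0L,
      retained_A = freq_keep(.data$plus1_A, .data$total_reads,
                             min_variant_freq, comparator) &
        .data$templated_plus1 != "A" & .data$total_reads > 0L,
      retained_T = freq_keep(.data$plus1_T, .data$total_reads,
                             min_variant_freq, comparator) &
        .data$templated_plus1 != "T" & .data$total_reads > 0L,
      pct_adenylated = dplyr::case_when(
        !.data$defined ~ NA_real_,
        .data$retained_A ~ 100 * .data$plus1_A / .data$total_reads,
        TRUE ~ 0),
      pct_uridylated = dplyr::case_when(
        !.data$defined ~ NA_real_,
        .data$retained_T ~ 100 * .data$plus1_T / .data$total_reads,
        TRUE ~ 0)
    ) %>%
    select("mirna_name", "library_id", "total_reads",
           dplyr::starts_with("plus1_"), "templated_plus1",
           "retained_A", "retained_T", "pct_adenylated", "pct_uridylated",
           "unambiguous_U_count", dplyr::starts_with("tail_"), "defined")
  out
}

#' Call +1-position additions for one miRNA in one library
#'
#' Tabulates NQS-passing reads extending at least one base beyond the
#' mature terminus by their +1 base, then retains a variant nucleotide iff
#' its frequency among all reads of the miRNA meets `min_variant_freq`
#' (comparator configurable) AND it differs from the templated genomic base
#' at flank offset 1. Percent adenylated/uridylated are 100 x retained
#' count / total reads, 0 when not retained, and NA (flagged by `defined`)
#' when the miRNA has no reads.
#'
#' @param alignments Alignment tibble for a single miRNA (and library).
#' @param catalog Catalog tibble.
#' @param params An [nqs_params()].
#' @param min_variant_freq Variant frequency threshold (default 1/1000).
#' @param comparator `"ge"` (default, frequency >= threshold) or `"gt"`.
#' @return A one-row profile tibble (counts, retained flags, percentages).
#' @export
call_plus1 <- function(alignments, catalog, params = nqs_params(),
                       min_variant_freq = 0.001,
                       comparator = c("ge", "gt")) {
  comparator <- match.arg(comparator)
  if (any(alignments$ambiguous)) {
    abort("call_plus1 expects unambiguous alignments only")
  }
  if (length(unique(alignments$mirna_name)) > 1L) {
    abort("call_plus1 expects alignments for a single miRNA")
  }
  mirna <- if (nrow(alignments) > 0) alignments$mirna_name[1] else
    catalog$name[1]
  profile_engine(alignments, catalog[catalog$name == mirna, , drop = FALSE],
                 params, min_variant_freq, comparator)
}

#' Count unambiguous uridylation events for one miRNA in one library
#'
#' An unambiguous uridylation is an NQS-passing read whose 3'-terminal base
#' is T while the templated base at that position (the mature sequence when
#' the read does not extend beyond the terminus, the genomic flank when it
#' does) is not T -- so the U can only be an enzymatic addition. For mature
#' sequences shared by several catalog entries the non-T condition must
#' hold for every entry's template.
#'
#' @inheritParams call_plus1
#' @return Integer count.
#' @export
detect_unambiguous_uridylation <- function(alignments, catalog,
                                           params = nqs_params()) {
  if (any(alignments$ambiguous)) {
    abort("detect_unambiguous_uridylation expects unambiguous alignments")
  }
  if (length(unique(alignments$mirna_name)) > 1L) {
    abort("detect_unambiguous_uridylation expects a single miRNA")
  }
  prof <- profile_engine(alignments, catalog, nqs_params_or(params),
                         min_variant_freq = 0.001, comparator = "ge")
  mirna <- if (nrow(alignments) > 0) alignments$mirna_name[1] else NULL
  if (is.null(mirna)) return(0L)
  as.integer(prof$unambiguous_U_count[prof$mirna_name == mirna])
}

nqs_params_or <- function(params) {
  if (inherits(params, "nqs_params")) params else do.call(nqs_params, params)
}

#' Build per-(miRNA, library) modification profiles
#'
#' Aggregates an alignment table (with a `library_id` column) into one
#' profile row per miRNA x library: total aligned reads, the NQS-passing
#' +1-base table, percent adenylated/uridylated under the retained-variant
#' rule, the unambiguous uridylation count, and tail-length counts over
#' overhangs 1-5.
#'
#' @param alignments Alignment tibble covering one or more libraries
#'   (column `library_id` required for multi-library tables).
#' @param catalog Catalog tibble.
#' @param params An [nqs_params()].
#' @param min_variant_freq Variant frequency threshold.
#' @param comparator `"ge"` or `"gt"` (see [call_plus1()]).
#' @param libraries Optional library universe for the output grid.
#' @return Profile tibble, one row per (miRNA, library).
#' @export
build_profiles <- function(alignments, catalog, params = nqs_params(),
                           min_variant_freq = 0.001,
                           comparator = c("ge", "gt"), libraries = NULL) {
  comparator <- match.arg(comparator)
  check_catalog(catalog)
  profile_engine(alignments, catalog, nqs_params_or(params),
                 min_variant_freq, comparator, libraries)
}

#' Most highly modified miRNAs
#'
#' Ranks miRNAs by their mean percent modified across libraries and returns
#' the top `n` in descending order.
#'
#' @param profiles Profile tibble from [build_profiles()].
#' @param nucleotide `"U"` or `"A"`.
#' @param n Number of miRNAs to keep.
#' @return Tibble `mirna_name`, `mean_pct` sorted descending.
#' @export
top_modified <- function(profiles, nucleotide = c("U", "A"), n = 40L) {
  nucleotide <- match.arg(nucleotide)
  col <- if (nucleotide == "U") "pct_uridylated" else "pct_adenylated"
  profiles %>%
    group_by(.data$mirna_name) %>%
    summarise(mean_pct = mean(.data[[col]], na.rm = TRUE),
              .groups = "drop") %>%
    filter(!is.nan(.data$mean_pct)) %>%
    arrange(dplyr::desc(.data$mean_pct), .data$mirna_name) %>%
    dplyr::slice_head(n = n)
}
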