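#' Align trimmed reads to a mature-miRNA catalog
#'
#' Reads are 5'-anchored to each mature sequence (no offset) and scored
#' under a two-class mismatch budget: bases in the read's terminal
#' `end3_window` nt, plus any bases beyond the mature terminus (compared to
#' the genomic flank), count toward the 3'-end class; all other mismatching
#' bases count as internal. A candidate is feasible iff internal mismatches
#' <= `max_internal`, 3'-end mismatches <= `max_end3` and the 3' overhang
#' does not exceed `max_overhang`. Among feasible candidates the winner has
#' the fewest total mismatches, then fewest internal, then longest overlap,
#' then the lexicographically smallest catalog name; a tie surviving the
#' first three keys marks the read `ambiguous` (such reads keep their
#' deterministic assignment for quantification but are excluded from tail
#' calling). N bases count as mismatches wherever compared.
#'
#' @param reads Read tibble with `read_id`, `sequence`, `qualities`
#'   (as produced by [demultiplex_and_trim()]).
#' @param catalog Catalog tibble (`name`, `mature_seq`, `flank3`).
#' @param max_internal,max_end3 Mismatch budgets (defaults 2 and 5).
#' @param end3_window Width of the read's 3'-end region in nt.
#' @param max_overhang Longest allowed 3' overhang in nt.
#' @return A list with `alignments` (tibble: read fields plus `mirna_name`,
#'   mismatch classes, `overlap_len`, `terminal_read_offset`,
#'   `overhang_seq`, `overhang_quals`, `terminal_read_base`, `ambiguous`),
#'   `unaligned` (read ids and sequences) and `stats` (input / aligned /
#'   unaligned / ambiguous counts and the aligned fraction).
#' @export
align_library <- function(reads, catalog, max_internal = 2L, max_end3 = 5L,
                          end3_window = 5L, max_overhang = 5L) {
  check_catalog(catalog)
  check_read_table(reads)
  cat_sorted <- catalog[order(catalog$name, method = "radix"), ]

  empty <- tibble(
    read_id = character(0), sequence = character(0), qualities = character(0),
    read_len = integer(0), mirna_name = character(0),
    internal_mismatches = integer(0), end3_mismatches = integer(0),
    overlap_len = integer(0), terminal_read_offset = integer(0),
    overhang_seq = character(0), overhang_quals = character(0),
    terminal_read_base = character(0), ambiguous = logical(0))
  if (nrow(reads) == 0L) {
    return(list(alignments = empty,
                unaligned = tibble(read_id = character(0),
                                   sequence = character(0)),
                stats = tibble(input = 0L, aligned = 0L, unaligned = 0L,
                               ambiguous = 0L, aligned_fraction = NA_real_)))
  }

  useq <- unique(reads$sequence)
  hit <- align_seqs_cpp(useq, cat_sorted$mature_seq, cat_sorted$flank3,
                        as.integer(max_internal), as.integer(max_end3),
                        as.integer(end3_window), as.integer(max_overhang))
  lookup <- as_tibble(hit)
  lookup$sequence <- useq
  lookup$mirna_name <- cat_sorted$name[lookup$entry]

  out <- left_join(reads, lookup, by = "sequence") %>%
    mutate(read_len = nchar(.data$sequence))
  aligned <- out %>%
    filter(!is.na(.data$entry)) %>%
    mutate(
      mature_len = .data$read_len - .data$terminal_read_offset,
      overhang_seq = ifelse(.data$terminal_read_offset > 0L,
                            substr(.data$sequence, .data$mature_len + 1L,
                                   .data$read_len), ""),
      overhang_quals = ifelse(.data$terminal_read_offset > 0L,
                              substr(.data$qualities, .data$mature_len + 1L,
                                     .data$read_len), ""),
      terminal_read_base = substr(.data$sequence, .data$read_len,
                                  .data$read_len)
    ) %>%
    select("read_id", "sequence", "qualities", "read_len", "mirna_name",
           "internal_mismatches", "end3_mismatches", "overlap_len",
           "terminal_read_offset", "overhang_seq", "overhang_quals",
           "terminal_read_base", "ambiguous")
  unaligned <- out %>%
    filter(is.na(.data$entry)) %>%
    select("read_id", "sequence")
  n_in <- nrow(reads); n_al <- nrow(aligned); n_un <- nrow(unaligned)
  n_amb <- sum(aligned$ambiguous)
  stats_tbl <- tibble(input = n_in, aligned = n_al, unaligned = n_un,
                      ambiguous = n_amb, aligned_fraction = n_al / n_in)
  list(alignments = aligned, unaligned = unaligned, stats = stats_tbl)
}

#' Align a single read
#'
#' Convenience wrapper around [align_library()] for one sequence.
#'
#' @param sequence A single DNA string.
#' @param catalog Catalog tibble.
#' @param qualities Optional Phred+33 quality string (defaults to maximal
#'   quality).
#' @param ... Passed to [align_library()].
#' @return A one-row alignment tibble, or a zero-row tibble if the read is
#'   unaligned under the mismatch budget.
#' @export
align_read <- function(sequence, catalog, qualities = NULL, ...) {
  stopifnot(length(sequence) == 1L)
  if (is.null(qualities)) qualities <- strrep("I", nchar(sequence))
  res <- align_library(tibble(read_id = "read", sequence = toupper(sequence),
                              qualities = qualities),
                       catalog, ...)
  res$alignments
}
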