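#' Build a barcode/adapter table for demultiplexing
#'
#' @param sample_id Character vector of sample labels.
#' @param adapter Character vector of full barcode-bearing 3' adapter
#'   sequences, one per sample.
#' @return A tibble with columns `sample_id`, `adapter`.
#' @export
barcode_table <- function(sample_id, adapter) {
  if (length(sample_id) == 0L) abort("barcode table must be nonempty")
  if (length(sample_id) != length(adapter)) {
    abort("sample_id and adapter must have equal length")
  }
  adapter <- toupper(adapter)
  if (anyDuplicated(adapter) > 0L) abort("adapter sequences must be distinct")
  if (anyDuplicated(sample_id) > 0L) abort("sample ids must be distinct")
  tibble(sample_id = as.character(sample_id), adapter = adapter)
}

# Leftmost position at which a prefix of `adapter` (exact match, minimum
# `min_prefix` nt, the full adapter where the read is long enough) occurs in
# each sequence. Returns NA where no position qualifies.
adapter_match_pos <- function(seqs, adapter, min_prefix = 8L) {
  L <- nchar(seqs)
  nA <- nchar(adapter)
  pos <- rep(NA_integer_, length(seqs))
  if (length(seqs) == 0L) return(pos)
  maxp <- max(L) - min(min_prefix, nA) + 1L
  if (maxp < 1L) return(pos)
  for (p in seq_len(maxp)) {
    open <- is.na(pos)
    if (!any(open)) break
    ext <- pmin(nA, L - p + 1L)
    ok <- open & ext >= min(min_prefix, nA) &
      substring(seqs, p, p + ext - 1L) == substring(adapter, 1L, ext)
    pos[ok] <- p
  }
  pos
}

#' Demultiplex reads by 3' adapter barcode and trim the adapter
#'
#' A read is assigned to a sample iff exactly one sample's adapter matches
#' it; the match rule is the leftmost exact occurrence of an adapter prefix
#' of at least `min_prefix` nt (the full adapter when the read is long
#' enough). Matched adapter bases are removed. Reads matching no adapter,
#' matching several, or whose trimmed insert falls outside
#' `[min_insert, max_insert]` are discarded with a reason code.
#'
#' @param reads Read tibble (`read_id`, `sequence`, `qualities`) or a FASTQ
#'   path.
#' @param table A [barcode_table()].
#' @param min_insert,max_insert Allowed insert length range in nt.
#' @param min_prefix Minimum adapter prefix that must match at the read end.
#' @return A list with `assigned` (trimmed reads with `sample_id` and
#'   `insert_len`) and `discarded` (reads with a `reason` of
#'   `"unrecognizable"`, `"ambiguous"` or `"insert_length"`). Every input
#'   read appears exactly once across the two tibbles.
#' @export
demultiplex_and_trim <- function(reads, table, min_insert = 16L,
                                 max_insert = 30L, min_prefix = 8L) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  check_read_table(reads)
  if (!is.data.frame(table) || nrow(table) == 0L) {
    abort("barcode table must be a nonempty data frame")
  }
  if (min_insert < 1L) abort("min_insert must be >= 1")

  empty_assigned <- tibble(read_id = character(0), sample_id = character(0),
                           sequence = character(0), qualities = character(0),
                           insert_len = integer(0))
  empty_discarded <- tibble(read_id = character(0), sequence = character(0),
                            reason = character(0))
  if (nrow(reads) == 0L) {
    return(list(assigned = empty_assigned, discarded = empty_discarded))
  }

  useq <- unique(reads$sequence)
  pos <- vapply(table$adapter,
                function(a) adapter_match_pos(useq, a, min_prefix),
                integer(length(useq)))
  pos <- matrix(pos, nrow = length(useq))
  nhit <- rowSums(!is.na(pos))
  hit_col <- ifelse(nhit == 1L, max.col(!is.na(pos), ties.method = "first"),
                    NA_integer_)
  hit_pos <- pos[cbind(seq_along(useq), ifelse(is.na(hit_col), 1L, hit_col))]
  hit_pos[is.na(hit_col)] <- NA_integer_
  insert_len <- hit_pos - 1L

  lookup <- tibble(
    sequence = useq,
    sample_id = ifelse(is.na(hit_col), NA_character_,
                       table$sample_id[hit_col]),
    insert_len = insert_len,
    reason = dplyr::case_when(
      nhit == 0L ~ "unrecognizable",
      nhit > 1L ~ "ambiguous",
      insert_len < min_insert | insert_len > max_insert ~ "insert_length",
      TRUE ~ NA_character_
    )
  )
  out <- left_join(reads, lookup, by = "sequence")
  assigned <- out %>%
    filter(is.na(.data$reason)) %>%
    mutate(sequence = substr(.data$sequence, 1L, .data$insert_len),
           qualities = substr(.data$qualities, 1L, .data$insert_len)) %>%
    select("read_id", "sample_id", "sequence", "qualities", "insert_len")
  discarded <- out %>%
    filter(!is.na(.data$reason)) %>%
    select("read_id", "sequence", "reason")
  stopifnot(nrow(assigned) + nrow(discarded) == nrow(reads))
  list(assigned = assigned, discarded = discarded)
}

#' Summarise a demultiplexing run
#'
#' @param demux Result of [demultiplex_and_trim()].
#' @return A tibble with one row per assigned sample and one per discard
#'   reason: `category`, `sample_id`, `reason`, `reads`, `fraction`.
#'   Fractions sum to 1 over the table. The total kept fraction is attached
#'   as attribute `kept_fraction`.
#' @export
preprocess_report <- function(demux) {
  total <- nrow(demux$assigned) + nrow(demux$discarded)
  by_sample <- demux$assigned %>%
    count(.data$sample_id, name = "reads") %>%
    mutate(category = paste0("assigned:", .data$sample_id),
           reason = NA_character_)
  by_reason <- demux$discarded %>%
    count(.data$reason, name = "reads") %>%
    mutate(category = paste0("discarded:", .data$reason),
           sample_id = NA_character_)
  out <- bind_rows(by_sample, by_reason) %>%
    mutate(fraction = if (total > 0) .data$reads / total else 0) %>%
    select("category", "sample_id", "reason", "reads", "fraction")
  attr(out, "kept_fraction") <-
    if (total > 0) nrow(demux$assigned) / total else 0
  out
}
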