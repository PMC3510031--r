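# Independent brute-force oracle for the read-to-miRNA assignment.
#
# Enumerates every catalog candidate for every read by materialising the
# full per-position template (mature body then genomic flank), classifies
# each mismatching position into internal vs 3'-end by direct position
# arithmetic, applies the feasibility budget, and ranks candidates with an
# explicit sort. Written as a separate implementation of the documented
# contract, not by calling the package's aligner.
oracle_align_all <- function(seqs, catalog, max_internal = 2L, max_end3 = 5L,
                             end3_window = 5L, max_overhang = 5L) {
  L <- unique(nchar(seqs))
  stopifnot(length(L) == 1L)
  n <- length(seqs)
  rc <- matrix(unlist(strsplit(seqs, "")), nrow = n, byrow = TRUE)

  cand <- lapply(seq_len(nrow(catalog)), function(k) {
    M <- nchar(catalog$mature_seq[k])
    off <- L - M
    if (off > max_overhang || off > nchar(catalog$flank3[k])) return(NULL)
    template <- character(L)
    for (p in seq_len(L)) {
      template[p] <- if (p <= M) {
        substr(catalog$mature_seq[k], p, p)
      } else {
        substr(catalog$flank3[k], p - M, p - M)
      }
    }
    is_end3 <- seq_len(L) > L - end3_window | seq_len(L) > M
    mism <- sweep(rc, 2, template, FUN = "!=")
    ni <- as.integer(mism[, !is_end3, drop = FALSE] %*% rep(1, sum(!is_end3)))
    ne <- as.integer(mism[, is_end3, drop = FALSE] %*% rep(1, sum(is_end3)))
    feasible <- ni <= max_internal & ne <= max_end3
    list(name = catalog$name[k], ni = ni, ne = ne, tot = ni + ne,
         ov = min(L, M), off = off, feasible = feasible)
  })
  cand <- Filter(Negate(is.null), cand)

  out <- data.frame(name = rep(NA_character_, n), ni = NA_integer_,
                    ne = NA_integer_, ov = NA_integer_, off = NA_integer_,
                    ambiguous = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    rows <- do.call(rbind, lapply(cand, function(ck) {
      if (!ck$feasible[i]) return(NULL)
      data.frame(name = ck$name, ni = ck$ni[i], ne = ck$ne[i],
                 tot = ck$tot[i], ov = ck$ov, off = ck$off,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(rows)) next
    rows <- rows[order(rows$tot, rows$ni, -rows$ov, rows$name,
                       method = "radix"), , drop = FALSE]
    b <- rows[1, ]
    out$name[i] <- b$name
    out$ni[i] <- b$ni
    out$ne[i] <- b$ne
    out$ov[i] <- b$ov
    out$off[i] <- b$off
    out$ambiguous[i] <- nrow(rows) > 1 && rows$tot[2] == b$tot &&
      rows$ni[2] == b$ni && rows$ov[2] == b$ov
  }
  out
}

# Two-entry toy catalog used for exhaustive aligner checks (lengths 6 and
# 8 so length-8 reads exercise overhangs 2 and 0).
toy_catalog <- function() {
  tibble::tibble(
    name = c("mirA", "mirB"),
    mature_seq = c("ACGTAC", "ACGTTCGA"),
    flank3 = c("TAGGCTAGGC", "GTTACGTTAC"),
    source = "toy")
}

# Build an alignment table row set directly (bypassing the aligner) for
# tail-calling tests: `n_plain` reads ending at the mature terminus plus
# one read per element of `tails` extending beyond it.
synthetic_alignments <- function(entry, n_plain, tails = character(0),
                                 tail_qual_char = "I",
                                 plain_qual_char = "I",
                                 library_id = "library",
                                 ambiguous = FALSE) {
  M <- nchar(entry$mature_seq)
  plain <- tibble::tibble(
    read_id = sprintf("p%06d", seq_len(n_plain)),
    qualities = strrep(plain_qual_char, M),
    read_len = M,
    mirna_name = entry$name,
    internal_mismatches = 0L, end3_mismatches = 0L, overlap_len = M,
    terminal_read_offset = 0L,
    overhang_seq = "", overhang_quals = "",
    terminal_read_base = substr(entry$mature_seq, M, M),
    ambiguous = ambiguous, library_id = library_id)
  if (length(tails) == 0L) return(plain)
  tl <- nchar(tails)
  tailed <- tibble::tibble(
    read_id = sprintf("t%06d", seq_along(tails)),
    qualities = paste0(strrep(plain_qual_char, M),
                       strrep(tail_qual_char, tl)),
    read_len = M + tl,
    mirna_name = entry$name,
    internal_mismatches = 0L, end3_mismatches = 0L, overlap_len = M,
    terminal_read_offset = tl,
    overhang_seq = tails, overhang_quals = strrep(tail_qual_char, tl),
    terminal_read_base = substr(tails, tl, tl),
    ambiguous = ambiguous, library_id = library_id)
  dplyr::bind_rows(plain, tailed)
}

# Reconstruct an emitted read from its truth annotation: mature + tail +
# barcode-bearing adapter, padded and truncated to the read length, then
# the recorded substitutions applied.
reconstruct_read <- function(truth_row, ref_truth, config) {
  mature <- ref_truth$mature_seq[match(truth_row$mirna_name, ref_truth$name)]
  adapter <- paste0(config$barcodes[truth_row$barcode_index + 1L],
                    config$adapter3_core)
  s <- substr(paste0(mature, truth_row$tail_seq, adapter,
                     strrep("A", config$read_length)),
              1L, config$read_length)
  if (nzchar(truth_row$errors)) {
    for (tok in strsplit(truth_row$errors, ",")[[1]]) {
      pos <- as.integer(sub("[ACGT]$", "", tok))
      base <- sub("^[0-9]+", "", tok)
      substr(s, pos, pos) <- base
    }
  }
  s
}

# Exact mid-p doubled-tail binomial p-value for a 2-category count.
exact_binom_midp <- function(x, n, p) {
  lo <- stats::pbinom(x - 1, n, p) + stats::dbinom(x, n, p) / 2
  hi <- stats::pbinom(x, n, p, lower.tail = FALSE) + stats::dbinom(x, n, p) / 2
  min(1, 2 * min(lo, hi))
}
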