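#' Read a FASTQ file into a read table
#'
#' Reads Phred+33 FASTQ into the tabular read representation used
#' throughout the package: one row per read with the base sequence and the
#' quality string.
#'
#' @param path Path to an uncompressed or gzipped FASTQ file.
#' @return A tibble with columns `read_id`, `sequence` and `qualities`
#'   (Phred+33 encoded, same length as `sequence`).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTQ file not found: ", path))
  x <- tryCatch(
    Biostrings::readQualityScaledDNAStringSet(path),
    error = function(e) abort(paste0("malformed FASTQ '", path, "': ",
                                     conditionMessage(e)))
  )
  tibble(
    read_id   = sub("\\s.*$", "", names(x)),
    sequence  = as.character(x),
    qualities = as.character(Biostrings::quality(x))
  )
}

#' Write a read table to FASTQ
#'
#' @param reads A data frame with columns `read_id`, `sequence`, `qualities`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  check_read_table(reads)
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  q <- Biostrings::PhredQuality(reads$qualities)
  qs <- Biostrings::QualityScaledDNAStringSet(x, q)
  Biostrings::writeQualityScaledXStringSet(qs, filepath = path)
  invisible(path)
}

# Validate the tabular read representation (SmallRNARead contract:
# one quality per base).
check_read_table <- function(reads, what = "reads") {
  need <- c("read_id", "sequence", "qualities")
  miss <- setdiff(need, names(reads))
  if (length(miss) > 0) {
    abort(paste0(what, " must have columns: ", paste(miss, collapse = ", ")))
  }
  bad <- which(nchar(reads$sequence) != nchar(reads$qualities))
  if (length(bad) > 0) {
    abort(paste0("malformed read record '", reads$read_id[bad[1]],
                 "': sequence and quality lengths differ"))
  }
  invisible(reads)
}

#' Decode a Phred+33 quality string to integer scores
#'
#' @param qualities Character vector of Phred+33 strings.
#' @return A list of integer vectors, one per input string.
#' @export
phred_scores <- function(qualities) {
  lapply(qualities, function(s) {
    if (nchar(s) == 0L) integer(0) else utf8ToInt(s) - 33L
  })
}

# Quality score at one position per read; `pos` is recycled/vectorised.
# Returns NA where pos is out of range.
phred_at <- function(qualities, pos) {
  ch <- substr(qualities, pos, pos)
  out <- rep(NA_integer_, length(ch))
  ok <- nchar(ch) == 1L
  if (any(ok)) out[ok] <- utf8ToInt(paste(ch[ok], collapse = "")) - 33L
  out
}

# Mean quality over a window [lo, hi] (already clipped to the read) per read.
phred_window_mean <- function(qualities, lo, hi) {
  win <- substr(qualities, lo, hi)
  vapply(win, function(s) {
    if (nchar(s) == 0L) NA_real_ else mean(utf8ToInt(s)) - 33
  }, numeric(1), USE.NAMES = FALSE)
}

# Encode integer Phred scores laid out read-major as fixed-width strings.
encode_phred_block <- function(scores, width) {
  stopifnot(length(scores) %% width == 0L)
  big <- rawToChar(as.raw(scores + 33L))
  n <- length(scores) %/% width
  starts <- seq.int(1L, by = width, length.out = n)
  substring(big, starts, starts + width - 1L)
}
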