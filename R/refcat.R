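#' Load and validate a mature-miRNA catalog with genomic 3' flanks
#'
#' Reads mature sequences from FASTA and their downstream genomic flanks
#' from either FASTA or a two-column TSV (`name`, `flank3`). U residues are
#' stored as T. Every mature record must have a flank record of the same
#' name; duplicate names and non-ACGTU characters are rejected with the
#' offending record named.
#'
#' @param mature_fasta Path to mature-sequence FASTA.
#' @param flanks Path to flank FASTA or TSV.
#' @param min_flank Minimum accepted flank length in nt.
#' @return A catalog tibble: `name`, `mature_seq`, `flank3`, `source`.
#' @export
load_catalog <- function(mature_fasta, flanks, min_flank = 10L) {
  mature <- read_named_seqs(mature_fasta)
  flank <- if (is_fasta_file(flanks)) {
    read_named_seqs(flanks)
  } else {
    tab <- utils::read.delim(flanks, header = FALSE, sep = "\t",
                             col.names = c("name", "seq"),
                             colClasses = "character")
    if (nrow(tab) > 0 && identical(tolower(tab$name[1]), "name")) {
      tab <- tab[-1, , drop = FALSE]
    }
    stats::setNames(tab$seq, tab$name)
  }
  dup <- names(mature)[duplicated(names(mature))]
  if (length(dup) > 0) {
    abort(paste0("duplicate mature record name: ", dup[1]))
  }
  missing <- setdiff(names(mature), names(flank))
  if (length(missing) > 0) {
    abort(paste0("no flank record for mature miRNA: ", missing[1]))
  }
  flank <- flank[names(mature)]
  norm <- function(x, what) {
    x <- chartr("u", "t", tolower(x))
    x <- toupper(x)
    bad <- grepl("[^ACGT]", x)
    if (any(bad)) {
      abort(paste0("non-ACGTU characters in ", what, " record: ",
                   names(mature)[which(bad)[1]]))
    }
    x
  }
  mature <- norm(mature, "mature")
  flank <- norm(flank, "flank")
  short <- nchar(flank) < min_flank
  if (any(short)) {
    abort(paste0("flank shorter than ", min_flank, " nt for: ",
                 names(mature)[which(short)[1]]))
  }
  tibble(name = names(mature), mature_seq = unname(mature),
         flank3 = unname(flank), source = mature_fasta)
}

is_fasta_file <- function(path) {
  first <- readLines(path, n = 1L)
  length(first) == 1L && startsWith(first, ">")
}

read_named_seqs <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Templated genomic base beyond the mature 3' terminus
#'
#' Offsets are 1-based into the genomic flank: offset 1 is the position one
#' nucleotide beyond the annotated mature 3' terminus (the "+1 position");
#' the mature terminus itself is position 0 and is not addressable here.
#'
#' @param entry A one-row catalog tibble (or list) with a `flank3` field.
#' @param offset Positive integer offset(s) beyond the mature terminus.
#' @return Character vector of single bases, one per offset.
#' @export
templated_base_at <- function(entry, offset) {
  flank <- if (is.data.frame(entry)) {
    if (nrow(entry) != 1L) abort("entry must be a single catalog record")
    entry$flank3
  } else {
    entry$flank3
  }
  if (is.null(flank) || length(flank) != 1L) {
    abort("entry must carry a single flank3 sequence")
  }
  offset <- as.integer(offset)
  if (any(offset < 1L)) {
    abort("offset must be >= 1 (0 is the mature terminus itself)")
  }
  if (any(offset > nchar(flank))) {
    abort(paste0("offset beyond available flank (", nchar(flank), " nt)"))
  }
  substring(flank, offset, offset)
}

# Internal: validate a catalog tibble built in code.
check_catalog <- function(catalog) {
  need <- c("name", "mature_seq", "flank3")
  miss <- setdiff(need, names(catalog))
  if (length(miss) > 0) {
    abort(paste0("catalog must have columns: ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(catalog$name) > 0L) {
    abort(paste0("duplicate catalog name: ",
                 catalog$name[duplicated(catalog$name)][1]))
  }
  invisible(catalog)
}

#' Write / read a catalog as TSV
#'
#' @param catalog A catalog tibble.
#' @param path File path.
#' @return `path` (write) or the catalog tibble (read).
#' @export
write_catalog <- function(catalog, path) {
  check_catalog(catalog)
  utils::write.table(catalog, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  out <- as_tibble(utils::read.delim(path, sep = "\t",
                                     colClasses = "character"))
  check_catalog(out)
  out
}
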