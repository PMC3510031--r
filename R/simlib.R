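#' Configuration for the paired WT/KO small-RNA library simulator
#'
#' Bundles every knob of the simulator: the reference catalog it fabricates,
#' per-miRNA tailing behaviour, the knockout effect, the sequencing error and
#' quality model, and the multiplexing layout. Defaults emulate a
#' three-pair, four-barcode multiplexed neonatal-liver style experiment with
#' miRNA-dominated inserts shorter than 30 nt and U/A tails of length 1-4.
#'
#' @param n_mirnas Number of miRNAs in the fabricated catalog.
#' @param mature_length_range Integer pair, min/max mature length in nt.
#' @param expression_logmean,expression_logsd Log-normal parameters for the
#'   relative abundance weights.
#' @param u_tail_prob_range,a_tail_prob_range Ranges for the per-miRNA
#'   wild-type probability that a transcript carries a 3' U (resp. A) tail.
#' @param tail_length_decay Geometric decay over tail lengths 1-4; the
#'   probability of tail length k is proportional to `tail_length_decay^(k-1)`.
#' @param ko_u_factor Multiplier applied to the U-tailing probability in the
#'   knockout genotype (default 0.3, a strong loss of uridylation).
#' @param ko_a_factor Multiplier on the A-tailing probability in the knockout
#'   (default 1, no effect).
#' @param frac_templated_t_flank Fraction of miRNAs whose genomic 3' flank
#'   starts with T, creating templated (ambiguous) U calls.
#' @param per_base_error_rate Substitution error rate per sequenced base.
#' @param quality_mean,quality_sd Gaussian Phred score model for correctly
#'   called bases, clipped to \[2, 40\].
#' @param error_quality_mean Mean Phred score at erroneous bases (same sd);
#'   lower than `quality_mean` so that quality-aware filtering is meaningful.
#' @param depth_per_library Reads per simulated library.
#' @param n_pairs Number of WT/KO library pairs.
#' @param barcodes Four distinct barcode sequences opening the 3' adapter.
#' @param adapter3_core Invariant 3' adapter sequence following the barcode.
#' @param read_length Fixed sequencer read length in nt.
#' @param flank_length Length of the fabricated genomic 3' flank per miRNA.
#' @param allow_ambiguous_families If `TRUE`, skip the pairwise
#'   distinguishability check on mature sequences.
#' @param seed Integer seed; all simulator randomness derives from it.
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(n_mirnas = 50L,
                              mature_length_range = c(20L, 23L),
                              expression_logmean = 0,
                              expression_logsd = 1.2,
                              u_tail_prob_range = c(0.01, 0.10),
                              a_tail_prob_range = c(0.01, 0.10),
                              tail_length_decay = 0.35,
                              ko_u_factor = 0.3,
                              ko_a_factor = 1.0,
                              frac_templated_t_flank = 0.25,
                              per_base_error_rate = 0.001,
                              quality_mean = 32,
                              quality_sd = 4,
                              error_quality_mean = 14,
                              depth_per_library = 2e5,
                              n_pairs = 3L,
                              barcodes = c("ATCACG", "CGATGT",
                                           "TTAGGC", "TGACCA"),
                              adapter3_core = "TCGTATGCCGTCTTCTGCTTG",
                              read_length = 36L,
                              flank_length = 12L,
                              allow_ambiguous_families = FALSE,
                              seed = 1L) {
  cfg <- list(
    n_mirnas = as.integer(n_mirnas),
    mature_length_range = as.integer(mature_length_range),
    expression_logmean = expression_logmean,
    expression_logsd = expression_logsd,
    u_tail_prob_range = u_tail_prob_range,
    a_tail_prob_range = a_tail_prob_range,
    tail_length_decay = tail_length_decay,
    ko_u_factor = ko_u_factor,
    ko_a_factor = ko_a_factor,
    frac_templated_t_flank = frac_templated_t_flank,
    per_base_error_rate = per_base_error_rate,
    quality_mean = quality_mean,
    quality_sd = quality_sd,
    error_quality_mean = error_quality_mean,
    depth_per_library = as.integer(depth_per_library),
    n_pairs = as.integer(n_pairs),
    barcodes = toupper(barcodes),
    adapter3_core = toupper(adapter3_core),
    read_length = as.integer(read_length),
    flank_length = as.integer(flank_length),
    allow_ambiguous_families = isTRUE(allow_ambiguous_families),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stop_if <- function(cond, msg) if (cond) abort(paste0("invalid config: ", msg))
  stop_if(cfg$n_mirnas < 1L, "n_mirnas must be positive")
  stop_if(length(cfg$mature_length_range) != 2L ||
            cfg$mature_length_range[1] > cfg$mature_length_range[2] ||
            cfg$mature_length_range[1] < 1L,
          "mature_length_range must be an increasing positive pair")
  probs <- c(cfg$u_tail_prob_range, cfg$a_tail_prob_range,
             cfg$frac_templated_t_flank, cfg$per_base_error_rate)
  stop_if(any(probs < 0 | probs > 1), "probabilities must lie in [0, 1]")
  stop_if(max(cfg$u_tail_prob_range) + max(cfg$a_tail_prob_range) > 1,
          "u and a tailing probabilities may not sum above 1")
  stop_if(cfg$tail_length_decay <= 0 || cfg$tail_length_decay >= 1,
          "tail_length_decay must lie in (0, 1)")
  stop_if(cfg$ko_u_factor <= 0 || cfg$ko_a_factor <= 0,
          "knockout factors must be positive")
  stop_if(cfg$depth_per_library < 0L, "depth_per_library must be >= 0")
  stop_if(cfg$n_pairs < 1L, "n_pairs must be positive")
  stop_if(length(cfg$barcodes) != 4L || anyDuplicated(cfg$barcodes) > 0L,
          "barcodes must be 4 distinct sequences")
  # barcodes must be pairwise non-prefix so demultiplexing is decidable
  for (i in seq_along(cfg$barcodes)) {
    for (j in seq_along(cfg$barcodes)) {
      if (i != j && startsWith(cfg$barcodes[j], cfg$barcodes[i])) {
        abort(paste0("invalid config: barcode '", cfg$barcodes[i],
                     "' is a prefix of '", cfg$barcodes[j], "'"))
      }
    }
  }
  max_insert <- cfg$mature_length_range[2] + 4L
  stop_if(max_insert + 8L > cfg$read_length,
          "read_length too short: the longest insert must leave >= 8 adapter nt")
  stop_if(cfg$flank_length < 10L, "flank_length must be >= 10")
  invisible(cfg)
}

# Distribution of tail lengths 1..4 under a geometric decay.
tail_length_probs <- function(decay) {
  p <- decay^(0:3)
  p / sum(p)
}

random_dna <- function(n, len) {
  vapply(len, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
}

hamming_prefix <- function(a, b) {
  l <- min(nchar(a), nchar(b))
  sum(strsplit(substr(a, 1, l), "")[[1]] != strsplit(substr(b, 1, l), "")[[1]])
}

#' Fabricate a mature-miRNA reference catalog with ground truth
#'
#' Generates `n_mirnas` mature sequences (pairwise Hamming distance >= 3
#' over their common prefix unless `allow_ambiguous_families`), a genomic 3'
#' flank for each, log-normal relative abundances, and per-miRNA wild-type
#' and knockout U/A tailing probabilities. Exactly
#' `round(frac_templated_t_flank * n_mirnas)` flanks begin with T so that
#' templated +1 U calls occur at a controlled rate.
#'
#' @param config A [simulation_config()].
#' @return A list with `catalog` (tibble: `name`, `mature_seq`, `flank3`,
#'   `source`) and `truth` (tibble adding `abundance`, `u_prob_wt`,
#'   `a_prob_wt`, `u_prob_ko`, `a_prob_ko`, `tail_len_probs` list-column).
#' @export
generate_reference <- function(config) {
  validate_sim_config(config)
  n <- config$n_mirnas
  rng <- config$mature_length_range
  # a mature must not, in any error-free read built from it, create an
  # adapter match other than the true one (a catalog sequence embedding an
  # adapter-like 8-mer would make all its reads ambiguous at demux)
  screen_ok <- function(m) {
    tails <- c("", strrep("T", 1:4), strrep("A", 1:4))
    adapters <- paste0(config$barcodes, config$adapter3_core)
    for (b in seq_along(adapters)) {
      reads <- substr(paste0(m, tails, adapters[b], strrep("A", config$read_length)),
                      1L, config$read_length)
      true_pos <- nchar(m) + nchar(tails) + 1L
      for (j in seq_along(adapters)) {
        pos <- adapter_match_pos(reads, adapters[j])
        ok <- if (j == b) !is.na(pos) & pos == true_pos else is.na(pos)
        if (!all(ok)) return(FALSE)
      }
    }
    TRUE
  }
  withr::with_seed(config$seed, {
    lens <- rng[1] + sample.int(rng[2] - rng[1] + 1L, n, replace = TRUE) - 1L
    max_tries <- 200L * n
    tries <- 0L
    propose <- function(l) {
      repeat {
        m <- random_dna(1, l)
        if (screen_ok(m)) return(m)
        tries <<- tries + 1L
        if (tries > max_tries) abort("cannot generate adapter-safe mature sequences")
      }
    }
    seqs <- vapply(lens, propose, character(1))
    if (!config$allow_ambiguous_families) {
      repeat {
        clash <- FALSE
        for (i in seq_len(n)) {
          for (j in seq_len(i - 1L)) {
            if (hamming_prefix(seqs[i], seqs[j]) < 3L) {
              tries <- tries + 1L
              if (tries > max_tries) {
                abort(paste0(
                  "cannot generate ", n, " pairwise distinguishable mature ",
                  "sequences of length ", rng[1], "-", rng[2],
                  "; reduce n_mirnas or widen the length range"))
              }
              seqs[i] <- propose(lens[i])
              clash <- TRUE
            }
          }
        }
        if (!clash) break
      }
    }
    flanks <- random_dna(n, rep(config$flank_length, n))
    k <- round(config$frac_templated_t_flank * n)
    t_idx <- if (k > 0) sample.int(n, k) else integer(0)
    first <- ifelse(seq_len(n) %in% t_idx, "T",
                    sample(c("A", "C", "G"), n, replace = TRUE))
    flanks <- paste0(first, substr(flanks, 2, config$flank_length))
    w <- rlnorm(n, config$expression_logmean, config$expression_logsd)
    u_wt <- runif(n, config$u_tail_prob_range[1], config$u_tail_prob_range[2])
    a_wt <- runif(n, config$a_tail_prob_range[1], config$a_tail_prob_range[2])
  })
  u_ko <- pmin(1, u_wt * config$ko_u_factor)
  a_ko <- pmin(1, a_wt * config$ko_a_factor)
  name <- sprintf("mir-sim-%03d", seq_len(n))
  catalog <- tibble(name = name, mature_seq = seqs, flank3 = flanks,
                    source = "simulated")
  truth <- tibble(
    name = name, mature_seq = seqs, flank3 = flanks,
    abundance = w / sum(w),
    u_prob_wt = u_wt, a_prob_wt = a_wt,
    u_prob_ko = u_ko, a_prob_ko = a_ko,
    tail_len_probs = rep(list(tail_length_probs(config$tail_length_decay)), n)
  )
  list(catalog = catalog, truth = truth)
}

#' Simulate one multiplexed small-RNA library
#'
#' Draws `depth` reads from the truth table's abundance distribution,
#' appends U/A tails according to the genotype-adjusted per-miRNA
#' probabilities, ligates the barcode-bearing 3' adapter, truncates to the
#' fixed read length, and injects substitution errors with
#' quality-consistent Phred scores. Every read carries a truth annotation
#' sufficient to reconstruct it exactly.
#'
#' @param truth Truth table from [generate_reference()].
#' @param genotype `"WT"` or `"KO"`.
#' @param barcode_index Integer in 0..3 selecting the 3' adapter barcode.
#' @param config The [simulation_config()].
#' @param depth Number of reads (default `config$depth_per_library`).
#' @param seed Integer seed for this library.
#' @param library_id Label recorded in read ids and truth annotations.
#' @return A list with `reads` (tibble: `read_id`, `sequence`, `qualities`)
#'   and `truth` (tibble: per-read source miRNA, genotype, tail, error
#'   records and emitted sequence).
#' @export
simulate_library <- function(truth, genotype, barcode_index, config,
                             depth = config$depth_per_library,
                             seed = config$seed,
                             library_id = paste0(genotype, barcode_index)) {
  validate_sim_config(config)
  if (!genotype %in% c("WT", "KO")) {
    abort(paste0("unknown genotype label '", genotype, "' (use WT or KO)"))
  }
  if (!barcode_index %in% 0:3) abort("barcode_index must be in 0..3")
  depth <- as.integer(depth)
  adapter <- paste0(config$barcodes[barcode_index + 1L], config$adapter3_core)
  L <- config$read_length
  empty <- list(
    reads = tibble(read_id = character(0), sequence = character(0),
                   qualities = character(0)),
    truth = tibble(read_id = character(0), library_id = character(0),
                   genotype = character(0), barcode_index = integer(0),
                   mirna_name = character(0), tail_seq = character(0),
                   tail_len = integer(0), insert_len = integer(0),
                   errors = character(0), sequence = character(0))
  )
  if (depth == 0L) return(empty)

  u_p <- if (genotype == "WT") truth$u_prob_wt else truth$u_prob_ko
  a_p <- if (genotype == "WT") truth$a_prob_wt else truth$a_prob_ko
  tl_probs <- truth$tail_len_probs[[1]]

  withr::with_seed(seed, {
    idx <- sample.int(nrow(truth), depth, replace = TRUE,
                      prob = truth$abundance)
    # at most one tail per read: U with prob u, A with prob a, else none
    r <- runif(depth)
    tail_base <- ifelse(r < u_p[idx], "T",
                        ifelse(r < u_p[idx] + a_p[idx], "A", ""))
    tail_len <- ifelse(tail_base == "", 0L,
                       sample.int(4L, depth, replace = TRUE, prob = tl_probs))
    tail_seq <- strrep(tail_base, tail_len)
    insert <- paste0(truth$mature_seq[idx], tail_seq)
    full <- substr(paste0(insert, adapter, strrep("A", L)), 1L, L)

    # substitution errors: sample distinct base positions genome-wide
    n_bases <- depth * L
    n_err <- rbinom(1L, n_bases, config$per_base_error_rate)
    err_read <- integer(0); err_pos <- integer(0); err_new <- character(0)
    if (n_err > 0L) {
      lin <- sample.int(n_bases, n_err)
      err_read <- (lin - 1L) %/% L + 1L
      err_pos <- (lin - 1L) %% L + 1L
      orig <- substr(full[err_read], err_pos, err_pos)
      others <- rbind(c("C", "G", "T"), c("A", "G", "T"),
                      c("A", "C", "T"), c("A", "C", "G"))
      pick <- sample.int(3L, n_err, replace = TRUE)
      err_new <- others[cbind(match(orig, c("A", "C", "G", "T")), pick)]
      remaining <- seq_len(n_err)
      while (length(remaining) > 0L) {
        take <- remaining[!duplicated(err_read[remaining])]
        ss <- full[err_read[take]]
        substr(ss, err_pos[take], err_pos[take]) <- err_new[take]
        full[err_read[take]] <- ss
        remaining <- setdiff(remaining, take)
      }
    }

    q <- as.integer(pmin(40, pmax(2, round(
      rnorm(n_bases, config$quality_mean, config$quality_sd)))))
    if (n_err > 0L) {
      q[(err_read - 1L) * L + err_pos] <- as.integer(pmin(40, pmax(2, round(
        rnorm(n_err, config$error_quality_mean, config$quality_sd)))))
    }
  })
  quals <- encode_phred_block(q, L)

  err_str <- rep("", depth)
  if (length(err_read) > 0L) {
    ord <- order(err_read, err_pos)
    lab <- paste0(err_pos[ord], err_new[ord])
    err_str[as.integer(names(tapply(lab, err_read[ord], length)))] <-
      tapply(lab, err_read[ord], paste, collapse = ",")
  }
  read_id <- sprintf("%s_%07d", library_id, seq_len(depth))
  list(
    reads = tibble(read_id = read_id, sequence = full, qualities = quals),
    truth = tibble(
      read_id = read_id, library_id = library_id, genotype = genotype,
      barcode_index = as.integer(barcode_index),
      mirna_name = truth$name[idx], tail_seq = tail_seq,
      tail_len = as.integer(tail_len),
      insert_len = nchar(truth$mature_seq[idx]) + as.integer(tail_len),
      errors = err_str, sequence = full)
  )
}

#' Simulate a full paired WT/KO multiplexed experiment
#'
#' Generates the reference, then `n_pairs` WT/KO library pairs with
#' deterministic per-library seeds derived from `config$seed` and barcode
#' assignments cycling over the four adapters. FASTQ files and a TSV
#' manifest/truth are written when `outdir` is given; the tibbles are always
#' returned in memory.
#'
#' @param config A [simulation_config()].
#' @param outdir Optional output directory for FASTQ + manifest + truth TSVs.
#' @return A list of class `mirtail_sim` with `catalog`, `truth`,
#'   `manifest` (one row per library: `library_id`, `pair_id`, `genotype`,
#'   `barcode_index`, `barcode`, `fastq`), `reads` (named list of read
#'   tibbles) and `read_truth` (per-read annotations, all libraries).
#' @export
simulate_experiment <- function(config, outdir = NULL) {
  validate_sim_config(config)
  ref <- generate_reference(config)
  manifest <- tidyr::crossing(pair_id = seq_len(config$n_pairs),
                              genotype = c("WT", "KO")) %>%
    arrange(.data$pair_id, dplyr::desc(.data$genotype)) %>%
    mutate(
      library_id = paste0(.data$genotype, .data$pair_id),
      barcode_index = as.integer((2L * (.data$pair_id - 1L) +
                                    (.data$genotype == "KO")) %% 4L),
      barcode = config$barcodes[.data$barcode_index + 1L],
      fastq = NA_character_
    ) %>%
    select("library_id", "pair_id", "genotype", "barcode_index",
           "barcode", "fastq")

  reads <- list()
  read_truth <- list()
  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, ]
    lib_seed <- (config$seed + 7919L * i) %% .Machine$integer.max
    sim <- simulate_library(ref$truth, m$genotype, m$barcode_index, config,
                            seed = lib_seed, library_id = m$library_id)
    reads[[m$library_id]] <- sim$reads
    read_truth[[m$library_id]] <- sim$truth
  }
  read_truth <- bind_rows(read_truth)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    manifest$fastq <- file.path(outdir, paste0(manifest$library_id, ".fastq"))
    purrr::walk2(manifest$library_id, manifest$fastq,
                 function(id, path) write_fastq(reads[[id]], path))
    utils::write.table(manifest, file.path(outdir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      ref$truth %>% mutate(tail_len_probs = vapply(
        .data$tail_len_probs, paste, character(1), collapse = ",")),
      file.path(outdir, "truth.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  structure(list(catalog = ref$catalog, truth = ref$truth,
                 manifest = manifest, reads = reads,
                 read_truth = read_truth, config = config),
            class = "mirtail_sim")
}
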