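entry_g <- tibble::tibble(name = "mirX",
                          mature_seq = "ACGTACGTACGTACGTACGTAC",
                          flank3 = "GTACCGGTAC")
entry_t <- tibble::tibble(name = "mirT",
                          mature_seq = "ACGTACGTACGTACGTACGTAC",
                          flank3 = "TTACCGGTAC")

test_that("nqs_pass implements both conditions with end truncation", {
  expect_true(nqs_pass(c(18, 20, 25, 16, 14), 3))
  expect_false(nqs_pass(c(40, 40, 19, 40, 40), 3))
  # window truncated at the read end: only two neighbours available
  expect_true(nqs_pass(c(30, 30, 25), 3))
  expect_false(nqs_pass(c(2, 2, 25), 3))   # window mean (2+2+25)/3 < 15
  expect_error(nqs_pass(c(30, 30), 5), "out of range")
  expect_error(nqs_params(window_length = 4), "odd")
})

test_that("raising a quality score never flips an NQS pass to fail", {
  withr::with_seed(19, {
    for (rep in 1:200) {
      q <- sample(2:40, 9, replace = TRUE)
      ctr <- sample(9, 1)
      before <- nqs_pass(q, ctr)
      j <- sample(9, 1)
      q2 <- q
      q2[j] <- min(40, q2[j] + sample(1:10, 1))
      if (before) expect_true(nqs_pass(q2, ctr))
    }
  })
})

test_that("+1 variants are retained by frequency against the templated base", {
  aln <- synthetic_alignments(entry_g, n_plain = 9985, tails = rep("T", 15))
  p <- call_plus1(aln, entry_g)
  expect_equal(p$total_reads, 10000L)
  expect_equal(p$plus1_T, 15L)
  expect_true(p$retained_T)
  expect_equal(p$pct_uridylated, 0.15)

  # below threshold: 5 per 10,000 is 0.05%
  p2 <- call_plus1(synthetic_alignments(entry_g, 9995, rep("T", 5)), entry_g)
  expect_false(p2$retained_T)
  expect_equal(p2$pct_uridylated, 0)

  # boundary: exactly 1 per 1,000 is retained under the reported rule,
  # not under the strict comparator
  aln10 <- synthetic_alignments(entry_g, 9990, rep("T", 10))
  expect_equal(call_plus1(aln10, entry_g)$pct_uridylated, 0.1)
  expect_equal(call_plus1(aln10, entry_g, comparator = "gt")$pct_uridylated,
               0)

  # no overhangs at all
  p0 <- call_plus1(synthetic_alignments(entry_g, 100), entry_g)
  expect_equal(p0$plus1_A + p0$plus1_C + p0$plus1_G + p0$plus1_T, 0L)
})

test_that("low-quality +1 bases are excluded by NQS", {
  # '0' encodes Phred 15, below the central minimum of 20
  aln <- synthetic_alignments(entry_g, 900, rep("T", 100),
                              tail_qual_char = "0")
  p <- call_plus1(aln, entry_g)
  expect_equal(p$plus1_T, 0L)
  expect_equal(p$pct_uridylated, 0)
})

test_that("templated +1 bases are never called as additions", {
  # flank starts TT: single and double U tails are genomically templated
  aln <- synthetic_alignments(entry_t, 500, c(rep("T", 40), rep("TT", 10)))
  p <- call_plus1(aln, entry_t)
  expect_equal(p$plus1_T, 50L)
  expect_false(p$retained_T)
  expect_equal(p$pct_uridylated, 0)
  expect_equal(detect_unambiguous_uridylation(aln, entry_t), 0L)
})

test_that("unambiguous uridylation requires a non-T template at the terminus", {
  # +1 U over a G flank: counted
  aln <- synthetic_alignments(entry_g, 100, rep("T", 7))
  expect_equal(detect_unambiguous_uridylation(aln, entry_g), 7L)
  # terminal A: never counted
  alnA <- synthetic_alignments(entry_g, 100, rep("A", 7))
  expect_equal(detect_unambiguous_uridylation(alnA, entry_g), 0L)
  # terminal substitution within the mature body (offset 0): mature ends C,
  # read ends T
  sub0 <- synthetic_alignments(entry_g, 1)
  sub0$terminal_read_base <- "T"
  expect_equal(detect_unambiguous_uridylation(sub0, entry_g), 1L)
  # multi-locus rule: a second entry sharing the mature sequence has a
  # T-starting flank, so +1 U is templated somewhere and must not count
  cat2 <- dplyr::bind_rows(entry_g, entry_t)
  expect_equal(detect_unambiguous_uridylation(aln, cat2), 0L)
})

test_that("build_profiles aggregates counts, tails and zero-read miRNAs", {
  aln <- synthetic_alignments(entry_g, 5, c("T", "T", "TT"))
  cat2 <- dplyr::bind_rows(
    entry_g, tibble::tibble(name = "mirZ",
                            mature_seq = "GGGGCCCCAAAATTTTGGGGCC",
                            flank3 = "ACGTACGTAC"))
  prof <- build_profiles(aln, cat2)
  px <- prof[prof$mirna_name == "mirX", ]
  expect_equal(px$tail_1, 2L)
  expect_equal(px$tail_2, 1L)
  expect_equal(px$total_reads, 8L)
  pz <- prof[prof$mirna_name == "mirZ", ]
  expect_equal(pz$total_reads, 0L)
  expect_false(pz$defined)
  expect_true(is.na(pz$pct_uridylated))

  # ambiguous reads count for totals but not for tail calling
  amb <- synthetic_alignments(entry_g, 0, c("T", "T"), ambiguous = TRUE)
  prof2 <- build_profiles(dplyr::bind_rows(aln, amb), cat2)
  px2 <- prof2[prof2$mirna_name == "mirX", ]
  expect_equal(px2$total_reads, 10L)
  expect_equal(px2$plus1_T, 3L)
})

test_that("profiles conserve aligned totals over a simulated experiment", {
  cfg <- simulation_config(n_mirnas = 10, depth_per_library = 4000,
                           seed = 43)
  sim <- simulate_experiment(cfg)
  btab <- barcode_table(paste0("bc", 0:3),
                        paste0(cfg$barcodes, cfg$adapter3_core))
  alns <- list()
  total_aligned <- 0L
  for (i in seq_len(nrow(sim$manifest))) {
    m <- sim$manifest[i, ]
    dm <- demultiplex_and_trim(sim$reads[[m$library_id]], btab)
    al <- align_library(dm$assigned, sim$catalog)
    alns[[m$library_id]] <- dplyr::mutate(al$alignments,
                                          library_id = m$library_id)
    total_aligned <- total_aligned + al$stats$aligned
  }
  prof <- build_profiles(dplyr::bind_rows(alns), sim$catalog,
                         libraries = sim$manifest$library_id)
  expect_equal(sum(prof$total_reads), total_aligned)
  expect_equal(nrow(prof), 10L * 6L)
})

test_that("top_modified sorts by mean percent in descending order", {
  prof <- tibble::tibble(
    mirna_name = rep(c("a", "b", "c"), each = 2),
    library_id = rep(c("L1", "L2"), 3),
    pct_uridylated = c(1, 3, 8, 6, 0, 0),
    pct_adenylated = c(5, 5, 0, 0, 9, 1))
  top <- top_modified(prof, "U", n = 2)
  expect_equal(top$mirna_name, c("b", "a"))
  expect_equal(top$mean_pct, c(7, 2))
  recompute <- tapply(prof$pct_uridylated, prof$mirna_name, mean)
  expect_equal(top$mean_pct,
               as.numeric(sort(recompute, decreasing = TRUE))[1:2])
  topA <- top_modified(prof, "A", n = 3)
  expect_equal(topA$mirna_name[1], "a")
})

test_that("false-positive retained variants are rare without true tailing", {
  cfg <- simulation_config(n_mirnas = 200, depth_per_library = 1e5,
                           u_tail_prob_range = c(0, 0),
                           a_tail_prob_range = c(0, 0),
                           per_base_error_rate = 0.001, seed = 53)
  ref <- generate_reference(cfg)
  lib <- simulate_library(ref$truth, "WT", 0, cfg, seed = 23)
  btab <- barcode_table(paste0("bc", 0:3),
                        paste0(cfg$barcodes, cfg$adapter3_core))
  dm <- demultiplex_and_trim(lib$reads, btab)
  al <- align_library(dm$assigned, ref$catalog)
  prof <- build_profiles(al$alignments, ref$catalog)
  fp <- mean(prof$retained_A | prof$retained_T, na.rm = TRUE)
  expect_lt(fp, 0.05)
})
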