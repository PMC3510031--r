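mk_manifest <- function(n_pairs = 3) {
  tibble::tibble(
    library_id = c(paste0("WT", 1:n_pairs), paste0("KO", 1:n_pairs)),
    pair_id = rep(1:n_pairs, 2),
    genotype = rep(c("WT", "KO"), each = n_pairs))
}

mk_profiles <- function(pct_wt, pct_ko, reads = 20000, nucleotide = "U",
                        n_pairs = 3) {
  man <- mk_manifest(n_pairs)
  pct_col <- if (nucleotide == "U") "pct_uridylated" else "pct_adenylated"
  other <- setdiff(c("pct_uridylated", "pct_adenylated"), pct_col)
  out <- tidyr::crossing(mirna_name = names(pct_wt),
                         library_id = man$library_id) %>%
    dplyr::mutate(total_reads = reads,
                  unambiguous_U_count = 1L)
  is_wt <- startsWith(out$library_id, "WT")
  out[[pct_col]] <- ifelse(is_wt, pct_wt[out$mirna_name],
                           pct_ko[out$mirna_name])
  out[[other]] <- 0.5
  out
}

test_that("RPM columns are per-library normalised to one million", {
  aln <- tibble::tibble(
    library_id = rep(c("L1", "L2"), c(4, 2)),
    mirna_name = c("a", "a", "b", "b", "a", "b"))
  rpm <- quantify_rpm(aln)
  sums <- tapply(rpm$rpm, rpm$library_id, sum)
  expect_equal(as.numeric(sums), c(1e6, 1e6))
  expect_equal(rpm$rpm[rpm$library_id == "L1" & rpm$mirna_name == "a"], 5e5)

  single <- quantify_rpm(tibble::tibble(library_id = "L1",
                                        mirna_name = "only"))
  expect_equal(single$rpm, 1e6)
  expect_error(
    quantify_rpm(tibble::tibble(library_id = "L1", mirna_name = "a",
                                total_reads = 0L)),
    "zero aligned")
})

test_that("genotype correlation has closed-form values on toy inputs", {
  man <- mk_manifest(1)
  rpm_id <- tidyr::crossing(mirna_name = c("a", "b", "c"),
                            library_id = man$library_id) %>%
    dplyr::mutate(reads = 10L,
                  rpm = rep(c(100, 200, 300), each = 2))
  expect_equal(genotype_correlation(rpm_id, man)$r, 1)

  rpm_anti <- tibble::tibble(
    mirna_name = rep(c("a", "b", "c"), 2),
    library_id = rep(c("WT1", "KO1"), each = 3),
    reads = 10L,
    rpm = c(1, 2, 3, 3, 2, 1))
  expect_equal(genotype_correlation(rpm_anti, man, scale = "linear")$r, -1)

  too_few <- rpm_id[rpm_id$mirna_name %in% c("a", "b"), ]
  expect_error(genotype_correlation(too_few, man), "fewer than 3")
})

test_that("chi-squared goodness of fit matches hand computation", {
  gof <- chisq_gof(c(179, 118), c(0.5, 0.5))
  expect_equal(gof$statistic, (179 - 148.5)^2 / 148.5 + (118 - 148.5)^2 / 148.5,
               tolerance = 1e-12)
  expect_equal(gof$statistic, 12.53, tolerance = 1e-3)
  expect_equal(gof$df, 1)
  expect_lt(gof$p_value, 0.001)
  expect_equal(gof$p_value, 4e-4, tolerance = 0.01)

  null <- chisq_gof(c(150, 150), c(0.5, 0.5))
  expect_equal(null$statistic, 0)
  expect_equal(null$p_value, 1)

  skew <- chisq_gof(c(20, 80), c(0.25, 0.75))
  expect_equal(skew$statistic, 4 / 3, tolerance = 1e-12)
  expect_equal(skew$p_value, 0.248, tolerance = 1e-3)
  expect_equal(skew$p_value, exact_binom_midp(20, 100, 0.25),
               tolerance = 0.01)

  expect_error(chisq_gof(c(1, 2, 3), c(0.5, 0.5)), "equal length")
  expect_error(chisq_gof(c(1, 2), c(0.6, 0.6)), "sum to 1")
})

test_that("chi-squared p agrees with an exact mid-p binomial oracle", {
  # agreement holds in the approximation's validity regime (expected
  # counts >= 10)
  withr::with_seed(67, {
    for (rep in 1:200) {
      n <- sample(20:50, 1)
      p <- sample(c(0.25, 0.5, 0.75), 1)
      if (min(n * p, n * (1 - p)) < 10) next
      x <- rbinom(1, n, p)
      got <- chisq_gof(c(x, n - x), c(p, 1 - p))$p_value
      expect_lt(abs(got - exact_binom_midp(x, n, p)), 0.03)
    }
  })
})

test_that("waterfall null and geometric-mean identities hold", {
  pct <- c(a = 2, b = 0.5, c = 1.2)
  wf <- waterfall(mk_profiles(pct, pct), mk_manifest(), "U",
                  min_reads = 10000, min_pct = 0.1)
  td <- tidy(wf)
  expect_true(all(td$included))
  expect_equal(td$geomean_ratio, rep(1, 3))
  g <- glance(wf)
  expect_equal(g$mean_log2_fc, 0)
  expect_equal(g$statistic, 0)
  expect_equal(g$p_value, 1)

  # per-pair ratios 2, 0.5, 1 have geometric mean 1
  prof <- mk_profiles(c(a = 1, b = 1), c(a = 1, b = 1))
  for (i in 1:3) {
    prof$pct_uridylated[prof$mirna_name == "a" &
                          prof$library_id == paste0("KO", i)] <-
      c(2, 0.5, 1)[i]
  }
  wf2 <- waterfall(prof, mk_manifest(), "U")
  expect_equal(tidy(wf2)$geomean_ratio[tidy(wf2)$mirna_name == "a"], 1,
               tolerance = 1e-12)
})

test_that("waterfall filters follow the wild-type read and percent gates", {
  pct <- c(lo = 2, hi = 2, faint = 0.05)
  prof <- mk_profiles(pct, pct / 2, reads = 20000)
  # 'lo' has only 3000 summed WT reads
  prof$total_reads[prof$mirna_name == "lo" &
                     startsWith(prof$library_id, "WT")] <- 1000L
  wf <- waterfall(prof, mk_manifest(), "U", min_reads = 10000,
                  min_pct = 0.1)
  td <- tidy(wf)
  expect_equal(td$exclusion_reason[td$mirna_name == "lo"], "min_reads")
  expect_equal(td$exclusion_reason[td$mirna_name == "faint"], "min_pct")
  expect_true(td$included[td$mirna_name == "hi"])
  expect_equal(glance(wf)$n_mirnas, 1L)
  expect_equal(glance(wf)$mean_log2_fc, -1)

  # nothing passes: empty summary with a warning
  expect_warning(
    wf0 <- waterfall(prof, mk_manifest(), "U", min_reads = 1e9),
    "no miRNA")
  expect_equal(glance(wf0)$n_mirnas, 0L)
})

test_that("zero percents fall back to the half-read pseudocount", {
  prof <- mk_profiles(c(a = 1), c(a = 0), reads = 10000)
  wf <- waterfall(prof, mk_manifest(), "U", min_reads = 1000,
                  min_pct = 0.1)
  td <- tidy(wf)
  # each pair ratio is (0 + 0.005) / (1 + 0.005)
  expect_equal(td$geomean_ratio, 0.005 / 1.005, tolerance = 1e-9)
})

test_that("length histogram testing reproduces Bonferroni arithmetic", {
  man <- mk_manifest(3)
  withr::with_seed(71, {
    lens <- purrr::map_dfr(man$library_id, function(id) {
      tibble::tibble(library_id = id,
                     length = sample(20:24, 2000, replace = TRUE))
    })
  })
  lh <- length_histogram_test(lens, man, lengths = 15:30)
  fr <- lh$histogram %>%
    dplyr::group_by(library_id) %>%
    dplyr::summarise(s = sum(fraction))
  expect_equal(fr$s, rep(1, 6))
  expect_equal(lh$contrasts$p_adj,
               pmin(1, lh$contrasts$p_raw * 16))
  # null case: Bonferroni controls the family-wise rate, so at most a
  # stray length can fall under 0.05
  expect_lte(sum(lh$contrasts$p_adj < 0.05), 1)

  man1 <- man[man$library_id %in% c("WT1", "KO1"), ]
  expect_warning(
    lh1 <- length_histogram_test(lens[lens$library_id %in%
                                        man1$library_id, ], man1),
    "fewer than 2")
  expect_false(lh1$tested)
  expect_s3_class(lh1$histogram, "tbl_df")
})

test_that("species counting restricts to the shared detection universe", {
  man <- mk_manifest(3)
  prof <- mk_profiles(c(a = 1, b = 1, c = 1), c(a = 1, b = 1, c = 1))
  prof$unambiguous_U_count <- 1L
  # 'b' loses its events in one KO library; 'c' is absent from one KO
  # library entirely
  prof$unambiguous_U_count[prof$mirna_name == "b" &
                             prof$library_id == "KO2"] <- 0L
  prof$total_reads[prof$mirna_name == "c" &
                     prof$library_id == "KO3"] <- 0L
  # tiny counts: chisq.test warns about the approximation, which is fine
  # for this fixture
  sp <- suppressWarnings(species_uridylation_counts(prof, man))
  expect_equal(sp$universe_size, 2L)
  expect_equal(sp$n_wt, 2L)
  expect_equal(sp$n_ko, 1L)
  expect_equal(sp$test$df, 1)

  sp2 <- suppressWarnings(
    species_uridylation_counts(prof, man, test = "contingency"))
  expect_s3_class(sp2, "species_counts")
})

test_that("simulated abundances are recovered by RPM quantification", {
  cfg <- simulation_config(n_mirnas = 50, depth_per_library = 1e6,
                           seed = 83)
  ref <- generate_reference(cfg)
  lib <- simulate_library(ref$truth, "WT", 0, cfg, depth = 1e6, seed = 29,
                          library_id = "WT1")
  btab <- barcode_table(paste0("bc", 0:3),
                        paste0(cfg$barcodes, cfg$adapter3_core))
  dm <- demultiplex_and_trim(lib$reads, btab)
  al <- align_library(dm$assigned, ref$catalog)
  rpm <- quantify_rpm(al$alignments %>% dplyr::mutate(library_id = "WT1"))
  j <- match(rpm$mirna_name, ref$truth$name)
  r <- cor(log10(rpm$rpm), log10(ref$truth$abundance[j] * 1e6))
  expect_gt(r, 0.99)
})
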