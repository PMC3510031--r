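#' Run the full pipeline on a simulated experiment
#'
#' Simulates the paired WT/KO multiplexed experiment described by `config`,
#' then runs every analysis stage: demultiplexing/trimming, alignment to
#' the fabricated catalog, modification profiling, and the comparative
#' statistics (RPM + genotype correlation, read-length ANOVA, A and U
#' waterfalls, species-level unambiguous-uridylation counts). When `outdir`
#' is given the result tables are written as TSV plus a JSON run summary.
#'
#' @param config A [simulation_config()].
#' @param outdir Optional report directory.
#' @param params An [nqs_params()].
#' @param min_variant_freq Variant frequency threshold for +1 calling.
#' @param min_reads,min_pct Waterfall wild-type inclusion filters.
#' @param lengths Length bins for the read-length histogram.
#' @return A list of class `mirtail_report` with the simulation inputs and
#'   every stage's outputs.
#' @export
run_all <- function(config, outdir = NULL, params = nqs_params(),
                    min_variant_freq = 0.001, min_reads = 10000,
                    min_pct = 0.1, lengths = 15:30) {
  stage <- "simulate"
  res <- tryCatch({
    sim <- simulate_experiment(config)
    btab <- barcode_table(
      sample_id = paste0("bc", 0:3),
      adapter = paste0(config$barcodes, config$adapter3_core))

    stage <- "trim"
    demux <- list(); alns <- list(); lens <- list(); astats <- list()
    reports <- list()
    for (i in seq_len(nrow(sim$manifest))) {
      m <- sim$manifest[i, ]
      dm <- demultiplex_and_trim(sim$reads[[m$library_id]], btab)
      kept <- dm$assigned %>%
        filter(.data$sample_id == paste0("bc", m$barcode_index))
      reports[[m$library_id]] <- preprocess_report(dm) %>%
        mutate(library_id = m$library_id)
      lens[[m$library_id]] <- tibble(library_id = m$library_id,
                                     length = kept$insert_len)
      stage <- "align"
      al <- align_library(kept, sim$catalog)
      alns[[m$library_id]] <- al$alignments %>%
        mutate(library_id = m$library_id)
      astats[[m$library_id]] <- al$stats %>%
        mutate(library_id = m$library_id)
      stage <- "trim"
    }
    alignments <- bind_rows(alns)

    stage <- "call"
    profiles <- build_profiles(alignments, sim$catalog, params,
                               min_variant_freq,
                               libraries = sim$manifest$library_id)

    stage <- "stats"
    rpm <- quantify_rpm(profiles)
    correlation <- genotype_correlation(rpm, sim$manifest)
    length_test <- length_histogram_test(bind_rows(lens), sim$manifest,
                                         lengths)
    wf_u <- waterfall(profiles, sim$manifest, "U", min_reads, min_pct)
    wf_a <- waterfall(profiles, sim$manifest, "A", min_reads, min_pct)
    species <- species_uridylation_counts(profiles, sim$manifest)

    list(config = config, catalog = sim$catalog, truth = sim$truth,
         manifest = sim$manifest, read_truth = sim$read_truth,
         preprocess = bind_rows(reports),
         alignment_stats = bind_rows(astats),
         alignments = alignments, profiles = profiles, rpm = rpm,
         correlation = correlation, length_test = length_test,
         waterfall_u = wf_u, waterfall_a = wf_a, species = species)
  }, error = function(e) {
    abort(paste0("pipeline failed at stage '", stage, "': ",
                 conditionMessage(e)))
  })

  if (!is.null(outdir)) write_report(res, outdir)
  structure(res, class = "mirtail_report")
}

write_tsv_plain <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_report <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_plain(res$manifest, file.path(outdir, "manifest.tsv"))
  write_tsv_plain(res$preprocess %>% select(-dplyr::any_of("reason")),
                  file.path(outdir, "preprocess.tsv"))
  write_tsv_plain(res$alignment_stats,
                  file.path(outdir, "alignment_stats.tsv"))
  write_tsv_plain(res$profiles, file.path(outdir, "profiles.tsv"))
  rpm_wide <- res$rpm %>%
    select("mirna_name", "library_id", "rpm") %>%
    tidyr::pivot_wider(names_from = "library_id", values_from = "rpm")
  write_tsv_plain(rpm_wide, file.path(outdir, "rpm_matrix.tsv"))
  write_tsv_plain(res$length_test$histogram,
                  file.path(outdir, "length_histogram.tsv"))
  if (!is.null(res$length_test$contrasts)) {
    write_tsv_plain(res$length_test$contrasts,
                    file.path(outdir, "length_contrasts.tsv"))
  }
  for (nt in c("u", "a")) {
    wf <- res[[paste0("waterfall_", nt)]]
    write_tsv_plain(tidy(wf) %>% select(-"ratios"),
                    file.path(outdir, paste0("waterfall_",
                                             toupper(nt), ".tsv")))
  }
  write_tsv_plain(
    tibble(n_wt = res$species$n_wt, n_ko = res$species$n_ko,
           universe = res$species$universe_size,
           statistic = res$species$test$statistic,
           p_value = res$species$test$p_value),
    file.path(outdir, "species_counts.tsv"))
  summary <- list(
    config = unclass(res$config),
    libraries = nrow(res$manifest),
    aligned = sum(res$alignment_stats$aligned),
    correlation_r = res$correlation$r,
    waterfall = list(U = as.list(glance(res$waterfall_u)),
                     A = as.list(glance(res$waterfall_a))),
    species = list(n_wt = res$species$n_wt, n_ko = res$species$n_ko,
                   p_value = res$species$test$p_value))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.mirtail_report <- function(x, ...) {
  cat("mirtail pipeline report\n")
  cat(sprintf("  libraries: %d (%d pairs), %d miRNAs, depth %d\n",
              nrow(x$manifest), x$config$n_pairs, x$config$n_mirnas,
              x$config$depth_per_library))
  cat(sprintf("  aligned reads: %d (%.1f%% of demultiplexed)\n",
              sum(x$alignment_stats$aligned),
              100 * sum(x$alignment_stats$aligned) /
                sum(x$alignment_stats$input)))
  cat(sprintf("  WT/KO abundance correlation r = %.3f (%d miRNAs)\n",
              x$correlation$r, x$correlation$n_mirnas))
  for (nt in c("u", "a")) {
    s <- glance(x[[paste0("waterfall_", nt)]])
    cat(sprintf("  %s waterfall: mean log2 FC %.3f [%.3f, %.3f], n = %d\n",
                toupper(nt), s$mean_log2_fc, s$ci_low, s$ci_high,
                s$n_mirnas))
  }
  cat(sprintf("  unambiguous-U species: WT %d vs KO %d (p = %.3g)\n",
              x$species$n_wt, x$species$n_ko, x$species$test$p_value))
  invisible(x)
}
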