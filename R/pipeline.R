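#' Assemble a pipeline run configuration
#'
#' Collects every stage parameter with defaults matching the thresholds used
#' throughout the package: retained read length 15-30 nt, mean base quality
#' strictly above 30 with at most 2 bases under Q20, unique sequences below
#' 10 reads discarded as ground noise, hairpins extended by 30 nt, sequences
#' mapping to more than 5 extra-hairpin genomic loci discarded, and target
#' scanning with a 7-nt seed, at least 14 base pairs and at most -20
#' kcal/mol. Unknown parameter names are rejected.
#'
#' @param ... overrides of the defaults.
#' @return named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    # simulation (used when no FASTQ input is given)
    n_hairpins = 50L, genome_length = 100000L, n_samples = 30L,
    single_mature_frac = 0.3, n_mornas = 5L, n_sisters = 3L,
    dispersion = 0.2,
    # preprocessing
    adapter = "TGGAATTCTCGGGTGCCAAGG", min_overlap = 3L,
    max_mismatch_rate = 0.1, min_len = 15L, max_len = 30L, mean_q = 30,
    low_q = 20, max_low = 2L, min_count = 10L,
    # reference / alignment
    flank = 30L, index_k = 5L, max_mismatches = 2L, max_extra_loci = 5L,
    # calling
    min_samples = 1L,
    # targets
    seed_len = 7L, max_seed_wobble = 1L, min_pairs = 14L, max_energy = -20,
    # inputs (NULL means simulate)
    fastq = NULL, genome_fa = NULL, annotation_gff3 = NULL,
    groups_table = NULL, transcripts_fa = NULL,
    seed = 1L)
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown configuration key(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  structure(cfg, class = "run_config")
}

#' Run the full small RNA-seq pipeline
#'
#' Orchestrates simulate (when no FASTQ input is configured) -> preprocess ->
#' align -> call -> quantify -> differential expression -> moRNA/miRNA
#' correlation -> (optional) target scan, writing stage outputs and a JSON
#' run report into `outdir`. A non-empty existing `outdir` is refused so
#' completed runs are never silently overwritten; the frozen configuration
#' (`config.json`) suffices to reproduce a run exactly.
#'
#' @param config a `run_config`.
#' @param outdir run directory (created; must not already contain a run).
#' @return invisibly, a list with the main in-memory results (`catalog`,
#'   `counts`, `de`, `report`, ...).
#' @export
run_pipeline <- function(config = run_config(), outdir) {
  stopifnot(inherits(config, "run_config"))
  if (dir.exists(outdir) && length(list.files(outdir)))
    stop("output directory ", outdir, " exists and is not empty; ",
         "refusing to overwrite a completed run")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(config), file.path(outdir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  report <- list()

  # --- stage: reference + reads -------------------------------------------
  simulate <- is.null(config$fastq)
  if (simulate) {
    ref <- simulate_reference(
      n_hairpins = config$n_hairpins, genome_length = config$genome_length,
      seed = config$seed, single_mature_frac = config$single_mature_frac,
      flank = config$flank)
    truth <- simulate_expression(
      ref, n_samples = config$n_samples, seed = config$seed + 1L,
      dispersion = config$dispersion, n_mornas = config$n_mornas,
      n_sisters = config$n_sisters)
    sim <- synthesize_reads(ref, truth, file.path(outdir, "sim"),
                            adapter = config$adapter,
                            seed = config$seed + 2L)
    write_reference(ref, file.path(outdir, "reference"))
    fastq <- sim$fastq
    groups <- truth$groups
  } else {
    if (is.null(config$genome_fa) || is.null(config$annotation_gff3))
      stop("stage reference: genome_fa and annotation_gff3 are required ",
           "when FASTQ input is given [ERR_REF_INPUT]")
    ref <- read_reference(config$genome_fa, config$annotation_gff3,
                          config$flank)
    fastq <- config$fastq
    if (is.null(names(fastq)))
      names(fastq) <- sub("\\.f(ast)?q(\\.gz)?$", "", basename(fastq))
    groups <- read_groups(config$groups_table)
    truth <- NULL
    missing <- setdiff(names(fastq), names(groups))
    if (length(missing))
      stop("stage validate: no group assigned to sample(s) ",
           paste(missing, collapse = ", "), " [ERR_GROUPS]")
    sim <- NULL
  }

  # --- stage: preprocess ---------------------------------------------------
  tables <- list()
  for (s in names(fastq)) {
    tables[[s]] <- preprocess_fastq(
      fastq[[s]], adapter = config$adapter,
      min_overlap = config$min_overlap,
      max_mismatch_rate = config$max_mismatch_rate,
      min_len = config$min_len, max_len = config$max_len,
      mean_q = config$mean_q, low_q = config$low_q,
      max_low = config$max_low, min_count = config$min_count)
  }
  st <- vapply(tables, function(tb) tb$stats, tables[[1L]]$stats)
  filt <- data.frame(sample = colnames(st), t(st), check.names = FALSE)
  utils::write.table(filt, file.path(outdir, "filter_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pct_pass <- 100 * sum(st["retained_reads", ]) / sum(st["reads_in", ])
  report$preprocess <- list(
    reads_in = sum(st["reads_in", ]),
    retained_reads = sum(st["retained_reads", ]),
    pct_reads_passing = pct_pass)

  # --- stage: align --------------------------------------------------------
  index <- build_index(ref, k = config$index_k)
  all_seqs <- sort(unique(unlist(lapply(tables, function(tb)
    names(tb$counts)))))
  mapres <- map_unique_sequences(index, all_seqs,
                                 max_mismatches = config$max_mismatches,
                                 max_extra_loci = config$max_extra_loci)
  report$align <- list(unique_sequences = length(all_seqs),
                       mapped = length(mapres$placements),
                       multimap_discarded = length(mapres$discarded),
                       unmapped = length(mapres$unmapped))

  # --- stage: call + quantify ---------------------------------------------
  catalog <- call_expressed_species(ref, mapres, tables,
                                    min_samples = config$min_samples)
  agg <- aggregate_counts(catalog, tables)
  write_catalog(catalog, agg, file.path(outdir, "species"))
  report$species <- as.list(table(catalog$species$class))

  # --- stage: normalization + DE -------------------------------------------
  raw <- agg$counts
  de <- NULL
  cume <- NULL
  correlations <- data.frame()
  if (nrow(raw) >= 2L && all(colSums(raw) > 0)) {
    sf <- size_factors(raw)
    y <- normalize_counts(raw, sf)
    cume <- cumulative_expression(y)
    utils::write.table(cume, file.path(outdir, "cumulative_expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    grp <- groups[colnames(raw)]
    if (length(unique(grp)) >= 2L && all(table(grp) >= 2L)) {
      phi <- estimate_dispersion(raw, grp, sf)
      de <- de_test(raw, grp, sf, phi)
      utils::write.table(de, file.path(outdir, "differential_expression.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report$de <- list(
        dispersion = phi,
        n_tests = nrow(de),
        n_q05_upper_quartile = sum(de$qvalue < 0.05 & de$upper_quartile))
    }
    # moRNA vs cognate miRNA (same hairpin arm) correlation
    mor <- grep("^moR-", rownames(y), value = TRUE)
    for (m in mor) {
      cg <- sub("^moR-", "miR-", m)
      if (cg %in% rownames(y)) {
        ct <- correlate_pairs(y[m, ], y[cg, ])
        correlations <- rbind(correlations, data.frame(
          morna = m, mirna = cg, tau = ct$tau, p_one_tailed = ct$p))
      }
    }
    if (nrow(correlations))
      utils::write.table(correlations,
                         file.path(outdir, "morna_mirna_correlation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- stage: targets (optional) -------------------------------------------
  target_hits <- NULL
  if (!is.null(config$transcripts_fa)) {
    tx <- Biostrings::readDNAStringSet(config$transcripts_fa)
    txv <- stats::setNames(as.character(tx), sub("\\s.*$", "", names(tx)))
    sp <- catalog$species
    mors <- stats::setNames(
      sp$representative_sequence[grepl("^moRNA", sp$class)],
      sp$species_id[grepl("^moRNA", sp$class)])
    mors <- mors[nchar(mors) >= 15L & nchar(mors) <= 35L]
    if (length(mors)) {
      target_hits <- scan_targets(mors, txv, seed_len = config$seed_len,
                                  max_seed_wobble = config$max_seed_wobble,
                                  min_pairs = config$min_pairs,
                                  max_energy = config$max_energy)
      utils::write.table(target_hits, file.path(outdir, "target_hits.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report$targets <- list(n_hits = nrow(target_hits))
    }
  }

  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(ref = ref, truth = truth, tables = tables, mapres = mapres,
                 catalog = catalog, agg = agg, de = de, cume = cume,
                 correlations = correlations, target_hits = target_hits,
                 report = report, outdir = outdir))
}
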