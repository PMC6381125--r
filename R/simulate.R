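#' @importFrom stats rlnorm rnbinom rpois rnorm runif median quantile var
NULL

# run code under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a miniature small-RNA reference
#'
#' Builds a synthetic genome carrying stem-loop (hairpin) precursors with
#' annotated mature miRNAs, in the style of a miRBase hairpin + annotation
#' bundle. Each hairpin is constructed as 5' arm + loop + reverse complement
#' of the arm, so the designed stem is a perfect helix of at least 16 bp that
#' structure prediction can recover. A configurable fraction of hairpins
#' carries only one annotated mature (its duplex partner is recorded as
#' ground truth for sister-miRNA discovery), one hairpin family is replicated
#' at several genomic loci to exercise family-level counting, and one decoy
#' sequence is planted at more than five loci to exercise the multimapping
#' noise filter.
#'
#' All coordinates are 1-based and closed. Mature intervals are given on the
#' extended hairpin (hairpin plus `flank` nt of genomic context on each side).
#'
#' @param n_hairpins total number of hairpin records (the replicated family
#'   counts once per copy).
#' @param genome_length length of the synthetic contig.
#' @param seed integer RNG seed; the same seed reproduces the bundle exactly.
#' @param single_mature_frac fraction of hairpin families annotated with only
#'   the 5p mature.
#' @param family_copies number of genomic copies of the replicated family.
#' @param n_decoy_loci number of genomic loci carrying the decoy sequence
#'   (must exceed the multimap threshold to be useful; default 6).
#' @param flank genomic flank added to each hairpin (default 30 nt).
#' @param contig contig name.
#' @return object of class `srna_reference`: list with `genome`, `contig`,
#'   `hairpins` (data.frame), `matures` (data.frame, extended-hairpin
#'   coordinates), `sisters_truth` (canonical duplex partner of the annotated
#'   mature for single-mature hairpins), `decoy`, and `flank`.
#' @export
simulate_reference <- function(n_hairpins = 50L, genome_length = 100000L,
                               seed = 1L, single_mature_frac = 0.3,
                               family_copies = 4L, n_decoy_loci = 6L,
                               flank = 30L, contig = "chrS") {
  stopifnot(n_hairpins >= 1L, genome_length >= 200L)
  family_copies <- min(family_copies, n_hairpins)
  .with_seed(seed, {
    n_families <- n_hairpins - family_copies + 1L
    fam <- list()
    for (f in seq_len(n_families)) {
      arm <- sample(30:48, 1L)
      loop <- sample(4:12, 1L)
      hp_len <- 2L * arm + loop
      arm5 <- .random_dna(arm)
      loop_seq <- .random_dna(loop)
      hp <- paste0(arm5, loop_seq, revcomp(arm5))
      o5 <- sample(2:6, 1L)
      m <- sample(20:23, 1L)
      m5 <- c(o5, o5 + m - 1L)
      # canonical duplex partner with 2-nt 3' overhangs on both strands
      s_start <- hp_len - o5 - m + 4L
      s_end <- hp_len - o5 + 3L
      dual <- f == 1L || runif(1L) > single_mature_frac
      fam[[f]] <- list(family = paste0("mir-", f), seq = hp, hp_len = hp_len,
                       arm = arm, loop = loop, m5 = m5,
                       m3 = c(s_start, s_end), dual = dual)
    }
    copies <- c(family_copies, rep(1L, n_families - 1L))

    genome <- sample(c("A", "C", "G", "T"), genome_length, replace = TRUE)
    placed <- matrix(numeric(0), 0, 2)  # occupied intervals incl. flanks
    place_seq <- function(len, what) {
      lo <- flank + 1L
      hi <- genome_length - len - flank
      if (hi < lo) stop("genome too short to place ", what,
                        " (need >= ", len + 2L * flank, " free nt)")
      for (try in 1:2000) {
        s <- sample(lo:hi, 1L)
        e <- s + len - 1L
        if (!nrow(placed) ||
            all(e + flank < placed[, 1L] | s - flank > placed[, 2L])) {
          placed <<- rbind(placed, c(s, e))
          return(s)
        }
      }
      stop("placement failed for ", what,
           ": could not find a non-overlapping locus after 2000 tries")
    }

    hp_rows <- list(); mat_rows <- list(); sis_rows <- list()
    idx <- 0L
    for (f in seq_len(n_families)) {
      fm <- fam[[f]]
      for (cp in seq_len(copies[f])) {
        idx <- idx + 1L
        hid <- if (copies[f] > 1L) paste0(fm$family, "-", cp) else fm$family
        s <- place_seq(fm$hp_len, paste0("hairpin ", hid))
        e <- s + fm$hp_len - 1L
        genome[s:e] <- strsplit(fm$seq, "", fixed = TRUE)[[1L]]
        hp_rows[[idx]] <- data.frame(
          hairpin_id = hid, family = fm$family, contig = contig,
          start = s, end = e, strand = "+", hp_len = fm$hp_len,
          stem_len = fm$arm, sequence = fm$seq, stringsAsFactors = FALSE)
        mname5 <- sub("^mir", "miR", fm$family)
        mat <- data.frame(
          hairpin_id = hid, family = fm$family,
          name = paste0(mname5, "-5p"), arm = "5p",
          start = fm$m5[1L] + flank, end = fm$m5[2L] + flank,
          stringsAsFactors = FALSE)
        if (fm$dual) {
          mat <- rbind(mat, data.frame(
            hairpin_id = hid, family = fm$family,
            name = paste0(mname5, "-3p"), arm = "3p",
            start = fm$m3[1L] + flank, end = fm$m3[2L] + flank,
            stringsAsFactors = FALSE))
        } else {
          sis_rows[[length(sis_rows) + 1L]] <- data.frame(
            hairpin_id = hid, family = fm$family,
            mature_name = paste0(mname5, "-5p"),
            start = fm$m3[1L] + flank, end = fm$m3[2L] + flank,
            arm = "3p", stringsAsFactors = FALSE)
        }
        mat_rows[[idx]] <- mat
      }
    }
    hairpins <- do.call(rbind, hp_rows)

    decoy_seq <- .random_dna(22L)
    decoy_loci <- data.frame(start = integer(0), end = integer(0))
    for (d in seq_len(n_decoy_loci)) {
      s <- place_seq(22L, "decoy locus")
      genome[s:(s + 21L)] <- strsplit(decoy_seq, "", fixed = TRUE)[[1L]]
      decoy_loci <- rbind(decoy_loci, data.frame(start = s, end = s + 21L))
    }

    genome <- paste0(genome, collapse = "")
    hairpins$ext_start <- pmax(1L, hairpins$start - flank)
    hairpins$ext_end <- pmin(genome_length, hairpins$end + flank)
    hairpins$extended_sequence <- substring(genome, hairpins$ext_start,
                                            hairpins$ext_end)
    structure(list(
      genome = genome, contig = contig, hairpins = hairpins,
      matures = do.call(rbind, mat_rows),
      sisters_truth = if (length(sis_rows)) do.call(rbind, sis_rows) else
        data.frame(),
      decoy = list(sequence = decoy_seq, loci = decoy_loci),
      flank = flank,
      params = list(n_hairpins = n_hairpins, genome_length = genome_length,
                    seed = seed, single_mature_frac = single_mature_frac,
                    family_copies = family_copies,
                    n_decoy_loci = n_decoy_loci)),
      class = "srna_reference")
  })
}

#' Default molecular-group assignment
#'
#' Assigns samples to the five molecular groups used throughout the package
#' (four aberration groups plus a rest group). For fewer than 10 samples a
#' two-group split is returned so every group keeps at least 2 samples.
#'
#' @param n_samples number of samples.
#' @return named character vector sample_id -> group.
#' @export
default_groups <- function(n_samples = 30L) {
  ids <- sprintf("S%02d", seq_len(n_samples))
  if (n_samples < 10L) {
    g <- rep(c("MAF", "other"), c(ceiling(n_samples / 2), floor(n_samples / 2)))
  } else {
    base <- c(t4p16 = 5, MAF = 8, t11q13 = 5, CCND1 = 6, other = 6) / 30
    sizes <- floor(base * n_samples)
    while (sum(sizes) < n_samples) sizes["other"] <- sizes["other"] + 1
    sizes <- pmax(sizes, 2L)
    while (sum(sizes) > n_samples) sizes["other"] <- sizes["other"] - 1L
    g <- rep(names(sizes), sizes)
  }
  stats::setNames(g[seq_len(n_samples)], ids)
}

#' Plant expression truth on a simulated reference
#'
#' Draws per-species baseline abundances from a heavy-tailed log-normal law
#' (so that a handful of species dominate the library), defines an isomiR
#' mixture for every annotated mature (exact sequence, small 5'/3' boundary
#' shifts, and substitution variants), plants low-abundance moRNAs flanking
#' selected matures plus one high-abundance moRNA, plants expressed sister
#' species on single-mature hairpins, and applies group-specific log2 fold
#' changes to selected species.
#'
#' @param ref an `srna_reference` from [simulate_reference()].
#' @param n_samples number of samples (>= 4).
#' @param groups named character vector sample -> group (>= 2 groups with
#'   >= 2 samples each); defaults to [default_groups()].
#' @param seed RNG seed.
#' @param dispersion negative-binomial dispersion used when sequencing reads.
#' @param mean_log,sd_log log-normal parameters of mature baseline abundance.
#' @param abundance_floor minimum mature baseline (keeps every planted species
#'   above the abundance noise filter in expectation).
#' @param exact_weight,shifted_weight,mismatch_weight isomiR mixture weights
#'   (normalized to sum to 1).
#' @param n_mornas number of planted moRNAs (the first is high-abundance).
#' @param n_sisters number of single-mature hairpins given an expressed
#'   sister species.
#' @param effects optional data.frame(species_id, group, log2fc) of planted
#'   effects; by default the high-abundance moRNA gets log2FC = 2 in "MAF",
#'   a second moRNA log2FC = 1.5 in "CCND1", and two miRNAs -1.5 / +1.5 in
#'   "t4p16" / "t11q13" (each only when that group exists).
#' @return object of class `expression_truth`: list with `records` (one row
#'   per planted unique sequence: record_id, species_id, class, hairpin,
#'   family, start, end, sequence, base_mean), `expected` (records x samples
#'   matrix of expected counts), `groups`, `effects`, `dispersion`,
#'   `isomir_mixture`.
#' @export
simulate_expression <- function(ref, n_samples = 30L, groups = NULL, seed = 1L,
                                dispersion = 0.2, mean_log = log(150),
                                sd_log = 1.5, abundance_floor = 170,
                                exact_weight = 0.40, shifted_weight = 0.45,
                                mismatch_weight = 0.15, n_mornas = 5L,
                                n_sisters = 3L, effects = NULL) {
  stopifnot(inherits(ref, "srna_reference"))
  if (is.null(groups)) groups <- default_groups(n_samples)
  stopifnot(length(groups) == n_samples)
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least 2 groups")
  if (any(tab < 2L)) stop("every group needs >= 2 samples (differential ",
                          "expression is untestable otherwise): ",
                          paste(names(tab)[tab < 2L], collapse = ", "))
  .with_seed(seed, {
    flank <- ref$flank
    ext_of <- function(hid) {
      ref$hairpins$extended_sequence[match(hid, ref$hairpins$hairpin_id)]
    }
    w <- c(exact_weight, shifted_weight, mismatch_weight)
    w <- w / sum(w)

    # one species per (family, mature name); use the first copy's hairpin
    mat <- ref$matures[!duplicated(paste(ref$matures$family,
                                         ref$matures$name)), , drop = FALSE]
    recs <- list()
    mix_list <- list()
    add_rec <- function(record_id, species_id, class, hid, family,
                        start, end, sequence, base_mean) {
      recs[[length(recs) + 1L]] <<- data.frame(
        record_id = record_id, species_id = species_id, class = class,
        hairpin_id = hid, family = family, start = start, end = end,
        sequence = sequence, base_mean = base_mean, stringsAsFactors = FALSE)
    }

    for (r in seq_len(nrow(mat))) {
      m <- mat[r, ]
      ext <- ext_of(m$hairpin_id)
      base <- pmax(rlnorm(1L, mean_log, sd_log), abundance_floor)
      mlen <- m$end - m$start + 1L
      # shifted variants: distinct (shift5, shift3) with length in [15, 30]
      shifts <- list()
      while (length(shifts) < 3L) {
        s5 <- sample(-3:3, 1L); s3 <- sample(-3:3, 1L)
        len <- mlen - s5 + s3
        if ((s5 != 0L || s3 != 0L) && len >= 15L && len <= 30L &&
            !any(vapply(shifts, function(x) all(x == c(s5, s3)), logical(1L))))
          shifts[[length(shifts) + 1L]] <- c(s5, s3)
      }
      sh_w <- runif(3L, 0.5, 1); sh_w <- w[2L] * sh_w / sum(sh_w)
      sh_w <- pmax(sh_w, 0.06)
      mm_w <- pmax(c(0.6, 0.4) * w[3L], 0.06)
      all_w <- c(w[1L], sh_w, mm_w)
      all_w <- all_w / sum(all_w)

      exact_seq <- substring(ext, m$start, m$end)
      add_rec(paste0(m$name, ".e"), m$name, "miRNA", m$hairpin_id, m$family,
              m$start, m$end, exact_seq, base * all_w[1L])
      for (k in 1:3) {
        s5 <- shifts[[k]][1L]; s3 <- shifts[[k]][2L]
        st <- m$start + s5; en <- m$end + s3
        add_rec(paste0(m$name, ".s", k), m$name, "isomiR", m$hairpin_id,
                m$family, st, en, substring(ext, st, en), base * all_w[1L + k])
      }
      # mismatched variants: 1 substitution anywhere; 2 in the 3' half
      subst <- function(s, pos) {
        v <- strsplit(s, "", fixed = TRUE)[[1L]]
        for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
        paste0(v, collapse = "")
      }
      p1 <- sample(mlen, 1L)
      half <- ceiling(mlen / 2)
      p2 <- sample((half + 1L):mlen, 2L)
      add_rec(paste0(m$name, ".m1"), m$name, "isomiR", m$hairpin_id, m$family,
              m$start, m$end, subst(exact_seq, p1), base * all_w[5L])
      add_rec(paste0(m$name, ".m2"), m$name, "isomiR", m$hairpin_id, m$family,
              m$start, m$end, subst(exact_seq, p2), base * all_w[6L])
      mix_list[[m$name]] <- data.frame(
        variant = c("exact", paste0("shift", 1:3), "mm1", "mm2"),
        prob = all_w)
    }

    # moRNAs: planted upstream of the 5p mature (and one downstream of a 3p
    # mature) on single-copy dual-mature hairpins
    hp_single_copy <- names(which(table(ref$hairpins$family) == 1L))
    dual_fams <- intersect(
      hp_single_copy,
      intersect(ref$matures$family[ref$matures$arm == "5p"],
                ref$matures$family[ref$matures$arm == "3p"]))
    n_mornas <- min(n_mornas, length(dual_fams))
    mor_fams <- sample(dual_fams, n_mornas)
    mor_means <- c(stats::quantile(vapply(recs, function(x) x$base_mean,
                                          numeric(1L)), 0.98),
                   pmax(rlnorm(max(0L, n_mornas - 1L), mean_log + log(0.05),
                               0.8), 40))
    for (k in seq_len(n_mornas)) {
      famk <- mor_fams[k]
      msub <- ref$matures[ref$matures$family == famk, ]
      hid <- msub$hairpin_id[1L]
      ext <- ext_of(hid)
      arm <- if (k %% 4L == 0L) "3p" else "5p"
      if (arm == "5p") {
        m5 <- msub[msub$arm == "5p", ]
        en <- m5$start - 1L; st <- en - 19L
      } else {
        m3 <- msub[msub$arm == "3p", ]
        st <- m3$end + 1L; en <- st + 19L
      }
      add_rec(paste0("moR-", sub("^mir-", "", famk), "-", arm),
              paste0("moR-", sub("^mir-", "", famk), "-", arm),
              paste0("moRNA_", arm), hid, famk, st, en,
              substring(ext, st, en), mor_means[k])
    }

    # expressed sisters on single-mature hairpins
    sis <- ref$sisters_truth
    n_sisters <- min(n_sisters, nrow(sis))
    if (n_sisters > 0L) {
      pick <- sample(seq_len(nrow(sis)), n_sisters)
      for (k in pick) {
        s <- sis[k, ]
        ext <- ext_of(s$hairpin_id)
        base <- pmax(rlnorm(1L, mean_log + log(0.3), 0.8), 60)
        add_rec(paste0(s$mature_name, "-sister"),
                paste0(s$mature_name, "-sister"), "new_miRNA",
                s$hairpin_id, s$family, s$start, s$end,
                substring(ext, s$start, s$end), base)
      }
    }

    records <- do.call(rbind, recs)
    stopifnot(!anyDuplicated(records$record_id))

    if (is.null(effects)) {
      effects <- data.frame(species_id = character(0), group = character(0),
                            log2fc = numeric(0))
      grp <- unique(groups)
      mor_ids <- records$species_id[grepl("^moR-", records$species_id)]
      mor_ids <- unique(mor_ids)
      if ("MAF" %in% grp && length(mor_ids) >= 1L)
        effects <- rbind(effects, data.frame(species_id = mor_ids[1L],
                                             group = "MAF", log2fc = 2))
      if ("CCND1" %in% grp && length(mor_ids) >= 2L)
        effects <- rbind(effects, data.frame(species_id = mor_ids[2L],
                                             group = "CCND1", log2fc = 1.5))
      mir_ids <- unique(records$species_id[records$class == "miRNA"])
      if ("t4p16" %in% grp && length(mir_ids) >= 1L)
        effects <- rbind(effects, data.frame(species_id = mir_ids[1L],
                                             group = "t4p16", log2fc = -1.5))
      if ("t11q13" %in% grp && length(mir_ids) >= 2L)
        effects <- rbind(effects, data.frame(species_id = mir_ids[2L],
                                             group = "t11q13", log2fc = 1.5))
    }

    expected <- matrix(rep(records$base_mean, n_samples),
                       nrow = nrow(records),
                       dimnames = list(records$record_id, names(groups)))
    for (e in seq_len(nrow(effects))) {
      rows <- records$species_id == effects$species_id[e]
      cols <- groups == effects$group[e]
      expected[rows, cols] <- expected[rows, cols] * 2^effects$log2fc[e]
    }

    structure(list(records = records, expected = expected, groups = groups,
                   effects = effects, dispersion = dispersion,
                   isomir_mixture = mix_list),
              class = "expression_truth")
  })
}

#' Synthesize adapter-ligated small RNA-seq reads
#'
#' Writes one single-end FASTQ per sample. Per-sample counts of each planted
#' record are drawn negative-binomially around the expected counts (Poisson
#' when `truth$dispersion == 0`); each read is the insert followed by the 3'
#' adapter, padded with random bases or truncated to the read length.
#' Phred+33 base qualities follow a per-position mean declining towards the
#' 3' end with Gaussian jitter. Configurable fractions of adapter-only,
#' unclipped, and low-quality reads plus low-count random "singleton" inserts
#' are injected as noise; noise reads are accounted separately from the
#' ground-truth manifest.
#'
#' @param ref an `srna_reference`.
#' @param truth an `expression_truth`.
#' @param outdir output directory (created; FASTQ, manifest and parameter
#'   files are written here).
#' @param adapter 3' adapter; defaults to the Illumina TruSeq small RNA
#'   adapter.
#' @param read_length sequencing read length (default 50).
#' @param seed RNG seed; the same seed reproduces FASTQ byte-identically.
#' @param frac_adapter_only,frac_unclipped,frac_lowq injected noise-read
#'   fractions (relative to the planted read count).
#' @param n_noise_seqs number of random low-count singleton insert sequences
#'   per sample.
#' @param decoy_mean expected per-sample count of reads from the planted
#'   multi-locus decoy sequence (class "noise"; they survive filtering and
#'   must be removed by the multimapping filter downstream).
#' @param q_start,q_end,q_sd quality profile: per-position mean declines
#'   linearly from `q_start` to `q_end` with jitter sd `q_sd`.
#' @return invisibly, a list with `fastq` (named file paths), `manifest`
#'   (data.frame of per-record realized counts per sample), `noise`
#'   (per-sample injected noise read counts), `manifest_file`.
#' @export
synthesize_reads <- function(ref, truth, outdir,
                             adapter = "TGGAATTCTCGGGTGCCAAGG",
                             read_length = 50L, seed = 1L,
                             frac_adapter_only = 0.03, frac_unclipped = 0.02,
                             frac_lowq = 0.02, n_noise_seqs = 30L,
                             decoy_mean = 30, q_start = 38, q_end = 31,
                             q_sd = 2.5) {
  stopifnot(inherits(ref, "srna_reference"), inherits(truth, "expression_truth"))
  if (!grepl("^[ACGT]+$", adapter)) stop("adapter must contain only A/C/G/T")
  max_insert <- max(nchar(truth$records$sequence))
  if (read_length <= max_insert + 3L)
    stop("read_length must exceed the longest insert plus a minimal ",
         "adapter overlap")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  samples <- names(truth$groups)
  phi <- truth$dispersion
  .with_seed(seed, {
    counts <- matrix(0L, nrow(truth$records), length(samples),
                     dimnames = list(truth$records$record_id, samples))
    fastq <- character(length(samples))
    noise_acct <- list()
    for (j in seq_along(samples)) {
      mu <- truth$expected[, j]
      n_i <- if (phi > 0) rnbinom(length(mu), mu = mu, size = 1 / phi)
             else rpois(length(mu), mu)
      counts[, j] <- n_i
      inserts <- rep(truth$records$sequence, n_i)
      n_planted <- length(inserts)

      n_ao <- round(frac_adapter_only * n_planted)
      n_uc <- round(frac_unclipped * n_planted)
      n_lq <- round(frac_lowq * n_planted)
      ao_reads <- vapply(seq_len(n_ao), function(i)
        substr(paste0(adapter, .random_dna(read_length)), 1L, read_length),
        character(1L))
      uc_reads <- character(n_uc)
      for (i in seq_len(n_uc)) {
        repeat {
          cand <- .random_dna(read_length)
          tr <- trim_adapter(cand, rep(35L, read_length), adapter)
          if (identical(tr$status, "unclipped")) { uc_reads[i] <- cand; break }
        }
      }
      lq_inserts <- if (n_lq > 0L && n_planted > 0L)
        sample(truth$records$sequence, n_lq, replace = TRUE) else character(0)
      noise_inserts <- vapply(seq_len(n_noise_seqs), function(i)
        .random_dna(sample(15:30, 1L)), character(1L))
      noise_counts <- sample(1:9, n_noise_seqs, replace = TRUE)
      sn_reads_ins <- rep(noise_inserts, noise_counts)
      n_decoy <- if (!is.null(ref$decoy) && decoy_mean > 0)
        rpois(1L, decoy_mean) else 0L
      decoy_ins <- rep(ref$decoy$sequence, n_decoy)

      good_ins <- c(inserts, decoy_ins, sn_reads_ins)
      mk_read <- function(ins) {
        r <- paste0(ins, adapter)
        if (nchar(r) < read_length) r <- paste0(r, .random_dna(read_length))
        substr(r, 1L, read_length)
      }
      good_reads <- vapply(good_ins, mk_read, character(1L),
                           USE.NAMES = FALSE)
      lq_reads <- vapply(lq_inserts, mk_read, character(1L),
                         USE.NAMES = FALSE)

      reads <- c(good_reads, lq_reads, ao_reads, uc_reads)
      n_reads <- length(reads)
      prof <- q_start + (q_end - q_start) * (seq_len(read_length) - 1L) /
        (read_length - 1L)
      qmat <- matrix(rnorm(n_reads * read_length, mean = rep(prof,
                     each = n_reads), sd = q_sd), nrow = n_reads)
      if (length(lq_reads))
        qmat[length(good_reads) + seq_along(lq_reads), ] <-
          qmat[length(good_reads) + seq_along(lq_reads), ] - 12
      qmat <- pmin(pmax(round(qmat), 2L), 40L)
      quals <- apply(qmat + 33L, 1L, intToUtf8)

      ord <- sample(n_reads)
      ids <- sprintf("%s_%06d", samples[j], seq_len(n_reads))
      fq <- file.path(outdir, paste0(samples[j], ".fastq"))
      writeLines(paste0("@", ids, "\n", reads[ord], "\n+\n", quals[ord]), fq)
      fastq[j] <- fq
      noise_acct[[samples[j]]] <- list(
        planted = n_planted, singleton_noise = length(sn_reads_ins),
        decoy = n_decoy, low_quality = n_lq, adapter_only = n_ao,
        unclipped = n_uc)
    }
    manifest <- cbind(truth$records[, c("record_id", "species_id", "class",
                                        "hairpin_id", "family", "start",
                                        "end", "sequence")],
                      as.data.frame(counts))
    mf <- file.path(outdir, "manifest.tsv")
    utils::write.table(manifest, mf, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(
      list(adapter = adapter, read_length = read_length, seed = seed,
           dispersion = phi, samples = samples,
           groups = as.list(truth$groups), noise = noise_acct),
      file.path(outdir, "parameters.json"), auto_unbox = TRUE, pretty = TRUE)
    invisible(list(fastq = stats::setNames(fastq, samples),
                   manifest = manifest, noise = noise_acct,
                   manifest_file = mf))
  })
}
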