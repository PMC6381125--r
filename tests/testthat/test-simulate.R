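test_that("reference construction honours its structural contract", {
  ref <- simulate_reference(n_hairpins = 12L, genome_length = 40000L,
                            seed = 5L)
  hp <- ref$hairpins
  expect_equal(nrow(hp), 12L)
  # every hairpin occurs verbatim at its genomic locus
  expect_true(all(substring(ref$genome, hp$start, hp$end) == hp$sequence))
  # designed stem: reverse-complement arms
  for (i in seq_len(nrow(hp))) {
    arm5 <- substr(hp$sequence[i], 1, hp$stem_len[i])
    arm3 <- substr(hp$sequence[i], hp$hp_len[i] - hp$stem_len[i] + 1,
                   hp$hp_len[i])
    expect_equal(arm3, revcomp(arm5))
    expect_gte(hp$stem_len[i], 16L)
    expect_gte(hp$hp_len[i], 60L)
    expect_lte(hp$hp_len[i], 120L)
  }
  # loci non-overlapping
  o <- order(hp$start)
  expect_true(all(hp$start[o][-1] > hp$end[o][-nrow(hp)]))
  # one family replicated with identical sequence at distinct loci
  fam <- table(hp$family)
  expect_gte(max(fam), 3L)
  copies <- hp[hp$family == names(which.max(fam)), ]
  expect_equal(length(unique(copies$sequence)), 1L)
  expect_equal(length(unique(copies$start)), nrow(copies))
  # decoy planted at more than five loci, outside hairpins
  expect_gte(nrow(ref$decoy$loci), 6L)
  expect_true(all(substring(ref$genome, ref$decoy$loci$start,
                            ref$decoy$loci$end) == ref$decoy$sequence))
  for (i in seq_len(nrow(ref$decoy$loci)))
    expect_true(all(ref$decoy$loci$end[i] < hp$start |
                      ref$decoy$loci$start[i] > hp$end))
  # 5p mature precedes 3p mature on dual hairpins
  for (h in unique(ref$matures$hairpin_id)) {
    m <- ref$matures[ref$matures$hairpin_id == h, ]
    if (nrow(m) == 2L)
      expect_lt(m$start[m$arm == "5p"], m$start[m$arm == "3p"])
  }
})

test_that("a single hairpin fits a tiny genome; impossible placements error", {
  ref <- simulate_reference(n_hairpins = 1L, genome_length = 1000L,
                            seed = 7L)
  expect_equal(nrow(ref$hairpins), 1L)
  expect_error(simulate_reference(n_hairpins = 50L, genome_length = 500L,
                                  seed = 1L), "place|short")
})

test_that("the reference is reproducible byte-for-byte under a fixed seed", {
  r1 <- simulate_reference(n_hairpins = 6L, genome_length = 15000L, seed = 1L)
  r2 <- simulate_reference(n_hairpins = 6L, genome_length = 15000L, seed = 1L)
  expect_identical(r1$genome, r2$genome)
  expect_identical(r1$hairpins, r2$hairpins)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_reference(r1, d1); write_reference(r2, d2)
  expect_identical(readLines(file.path(d1, "hairpins.fa")),
                   readLines(file.path(d2, "hairpins.fa")))
})

test_that("planted expression obeys the requested design", {
  ref <- tiny_ref()
  # null configuration: no effects -> identical expected counts everywhere
  tr0 <- simulate_expression(ref, n_samples = 6L, seed = 2L,
                             effects = data.frame(species_id = character(0),
                                                  group = character(0),
                                                  log2fc = numeric(0)))
  expect_true(all(tr0$expected == tr0$expected[, 1]))
  # a 2-log2FC species has exactly 4x expected counts in its group
  tr <- simulate_expression(ref, n_samples = 8L,
                            groups = stats::setNames(
                              rep(c("MAF", "other"), each = 4),
                              sprintf("S%02d", 1:8)),
                            seed = 3L,
                            effects = data.frame(species_id = "moR-target",
                                                 group = "MAF", log2fc = 2))
  # effects reference planted moRNA ids; rebuild with a real species id
  mor <- grep("^moR-", unique(tr$records$species_id), value = TRUE)[1]
  tr <- simulate_expression(ref, n_samples = 8L,
                            groups = stats::setNames(
                              rep(c("MAF", "other"), each = 4),
                              sprintf("S%02d", 1:8)),
                            seed = 3L,
                            effects = data.frame(species_id = mor,
                                                 group = "MAF", log2fc = 2))
  rows <- tr$records$species_id == mor
  maf <- tr$groups == "MAF"
  expect_equal(unname(tr$expected[rows, maf][1] /
                        tr$expected[rows, !maf][1]), 4)
  # determinism
  tr2 <- simulate_expression(ref, n_samples = 8L,
                             groups = stats::setNames(
                               rep(c("MAF", "other"), each = 4),
                               sprintf("S%02d", 1:8)),
                             seed = 3L,
                             effects = data.frame(species_id = mor,
                                                  group = "MAF", log2fc = 2))
  expect_identical(tr$expected, tr2$expected)
  # isomiR mixtures are proper distributions
  for (mx in tr$isomir_mixture) expect_equal(sum(mx$prob), 1)
  # groups below two samples are rejected
  expect_error(simulate_expression(ref, n_samples = 3L,
                                   groups = stats::setNames(
                                     c("A", "A", "B"), c("a", "b", "c")),
                                   seed = 1L), ">= 2 samples")
})

test_that("read synthesis writes deterministic, adapter-ligated reads", {
  ref <- tiny_ref()
  tr <- simulate_expression(ref, n_samples = 4L,
                            groups = stats::setNames(
                              rep(c("MAF", "other"), each = 2),
                              sprintf("S%02d", 1:4)), seed = 2L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- synthesize_reads(ref, tr, d1, seed = 9L)
  s2 <- synthesize_reads(ref, tr, d2, seed = 9L)
  expect_identical(readLines(s1$fastq[1]), readLines(s2$fastq[1]))
  expect_identical(readLines(s1$manifest_file), readLines(s2$manifest_file))

  lines <- readLines(s1$fastq[1])
  reads <- lines[seq(2, length(lines), by = 4)]
  expect_true(all(nchar(reads) == 50L))
  # every manifest record's reads appear with the insert followed by the
  # adapter
  rec <- s1$manifest[1, ]
  expected_prefix <- substr(paste0(rec$sequence, "TGGAATTCTCGGGTGCCAAGG"),
                            1, 50)
  expect_gte(sum(startsWith(reads, expected_prefix)), rec$S01)
  # injected adapter-only reads start with the adapter at position one
  n_ao <- jsonlite::read_json(file.path(d1, "parameters.json"))$
    noise$S01$adapter_only
  expect_equal(sum(startsWith(reads, "TGGAATTCTCGGGTGCCAAGG")), n_ao)
  # manifest counts equal the number of planted (non-noise) reads written
  pj <- jsonlite::read_json(file.path(d1, "parameters.json"))
  expect_equal(sum(s1$manifest$S01), pj$noise$S01$planted)
  nz <- pj$noise$S01
  expect_equal(length(reads),
               nz$planted + nz$singleton_noise + nz$decoy + nz$low_quality +
                 nz$adapter_only + nz$unclipped)
  expect_error(synthesize_reads(ref, tr, withr::local_tempdir(),
                                adapter = "TGGAANX", seed = 1),
               "adapter")
})

test_that("zero dispersion gives Poisson-like counts around the mean", {
  ref <- simulate_reference(n_hairpins = 2L, genome_length = 5000L,
                            seed = 21L)
  tr <- simulate_expression(ref, n_samples = 4L,
                            groups = stats::setNames(
                              rep(c("A", "B"), each = 2),
                              sprintf("S%02d", 1:4)),
                            seed = 22L, dispersion = 0)
  rec1 <- tr$records$record_id[1]
  mu <- tr$expected[rec1, 1]
  draws <- numeric(0)
  for (sd in 1:30) {
    d <- withr::local_tempdir()
    s <- synthesize_reads(ref, tr, d, seed = sd, decoy_mean = 0,
                          n_noise_seqs = 0L, frac_adapter_only = 0,
                          frac_unclipped = 0, frac_lowq = 0)
    draws <- c(draws, as.numeric(s$manifest[s$manifest$record_id == rec1,
                                            names(tr$groups)]))
  }
  expect_equal(mean(draws), mu, tolerance = 0.1)
  expect_gt(var(draws) / mean(draws), 0.6)
  expect_lt(var(draws) / mean(draws), 1.6)
})
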