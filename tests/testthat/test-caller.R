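# a 120-nt extended hairpin frame with a 5p and a 3p mature
MAT2 <- data.frame(name = c("miR-x-5p", "miR-x-3p"), arm = c("5p", "3p"),
                   start = c(31L, 81L), end = c(52L, 102L),
                   is_sister = c(FALSE, FALSE), stringsAsFactors = FALSE)

test_that("classification follows the exact > isomiR > moRNA precedence", {
  # identity
  expect_equal(classify_placement(31L, 52L, integer(0), MAT2)$class,
               "miRNA_exact")
  # 2-nt 5' extension
  r <- classify_placement(29L, 52L, integer(0), MAT2)
  expect_equal(r$class, "isomiR")
  expect_equal(r$shift5, -2L)
  expect_equal(r$shift3, 0L)
  # two mismatches in the 5' half are not tolerated; the read covers the
  # mature, so it is not a moRNA either
  expect_equal(classify_placement(31L, 52L, c(3L, 8L), MAT2)$class,
               "unclassified")
  # two mismatches in the 3' half are tolerated
  expect_equal(classify_placement(31L, 52L, c(14L, 20L), MAT2)$class,
               "isomiR")
  # central nucleotide strictly upstream of the 5p mature start
  r <- classify_placement(13L, 33L, integer(0), MAT2)
  expect_equal(r$class, "moRNA_5p")
  expect_equal(r$central, 23L)
  # central nucleotide strictly downstream of the 3p mature end
  r <- classify_placement(93L, 114L, integer(0), MAT2)
  expect_equal(r$class, "moRNA_3p")
  expect_equal(r$central, 103L)
})

test_that("a read whose centre equals the 5p mature start is not a moRNA", {
  # len 21 -> central = start + 10; central == 31 when start == 21
  r <- classify_placement(21L, 41L, c(1L, 2L), MAT2)  # mismatches block isomiR
  expect_equal(r$central, 31L)
  expect_false(r$class == "moRNA_5p")
  # one position further upstream the centre crosses the boundary
  r <- classify_placement(20L, 40L, c(1L, 2L), MAT2)
  expect_equal(r$central, 30L)
  expect_equal(r$class, "moRNA_5p")
})

test_that("hairpins without matures yield unclassified calls", {
  none <- MAT2[0, ]
  expect_equal(classify_placement(31L, 52L, integer(0), none)$class,
               "unclassified")
})

test_that("classifier matches the brute-force oracle over the full frame", {
  cases <- 0L
  for (len in c(15L, 18L, 22L, 26L, 30L)) {
    for (start in seq_len(120L - len + 1L)) {
      end <- start + len - 1L
      mmsets <- c(list(integer(0)),
                  lapply(seq_len(len), identity),
                  list(c(2L, len - 1L), c(len - 1L, len)))
      for (mm in mmsets) {
        got <- classify_placement(start, end, mm, MAT2)
        want <- oracle_classify(start, end, mm, MAT2)
        expect_identical(got$class, want$class)
        if (got$class %in% c("miRNA_exact", "isomiR"))
          expect_identical(got$mature, want$mature)
        cases <- cases + 1L
      }
    }
  }
  expect_gt(cases, 10000L)
})

test_that("sister discovery recovers the planted duplex partner", {
  ref <- tiny_ref()
  sis <- ref$sisters_truth
  expect_gt(nrow(sis), 0L)
  for (i in seq_len(nrow(sis))) {
    h <- ref$hairpins[ref$hairpins$hairpin_id == sis$hairpin_id[i], ]
    m <- ref$matures[ref$matures$hairpin_id == sis$hairpin_id[i], ]
    got <- discover_sister(h$extended_sequence, m$start, m$end)
    expect_equal(got$start, sis$start[i], info = sis$hairpin_id[i])
    expect_equal(got$end, sis$end[i], info = sis$hairpin_id[i])
    expect_equal(got$arm, "3p")
  }
})

test_that("an unpaired (loop-placed) mature yields no sister", {
  arm <- strrep("G", 20)
  hp <- paste0(arm, strrep("A", 22), revcomp(arm))
  expect_null(discover_sister(hp, 23L, 40L))
  expect_error(discover_sister(hp, 50L, 80L), "outside")
})

test_that("species catalog aggregates families once and splits variants", {
  ref <- simulate_reference(n_hairpins = 4L, genome_length = 15000L,
                            seed = 31L, family_copies = 3L,
                            single_mature_frac = 0)
  idx <- build_index(ref, k = 5L)
  fam <- names(which.max(table(ref$hairpins$family)))
  h <- ref$hairpins[ref$hairpins$family == fam, ][1, ]
  m <- ref$matures[ref$matures$hairpin_id == h$hairpin_id, ]
  m5 <- m[m$arm == "5p", ]
  exact <- substring(h$extended_sequence, m5$start, m5$end)
  shifted <- substring(h$extended_sequence, m5$start + 2L, m5$end + 1L)
  mm1 <- exact
  substr(mm1, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(mm1, 5, 5))[1]
  morna <- substring(h$extended_sequence, m5$start - 20L, m5$start - 1L)
  loop_seq <- substring(h$extended_sequence, m5$end + 3L, m5$end + 20L)

  tab <- list(
    S01 = c(stats::setNames(c(60L, 25L, 15L, 30L, 12L),
                            c(exact, shifted, mm1, morna, loop_seq))),
    S02 = c(stats::setNames(c(40L, 10L), c(exact, morna))))
  mp <- map_unique_sequences(idx, unique(names(c(tab$S01, tab$S02))))
  cat <- call_expressed_species(ref, mp, tab)
  agg <- aggregate_counts(cat, tab)

  mir5 <- sub("^mir", "miR", paste0(fam, "-5p"))
  mor5 <- paste0("moR-", sub("^mir-", "", fam), "-5p")
  expect_true(mir5 %in% cat$species$species_id)
  expect_true(mor5 %in% cat$species$species_id)
  # family copies never duplicate a species
  expect_equal(sum(cat$species$species_id == mir5), 1L)
  # miRNA signal = exact + isomiR members
  expect_equal(unname(agg$counts[mir5, "S01"]), 60L + 25L + 15L)
  expect_equal(unname(agg$counts[mor5, ]), c(30L, 10L))
  comp <- agg$composition[agg$composition$species_id == mir5, ]
  expect_equal(comp$exact_fraction, 100 / 140)
  expect_equal(comp$shifted_fraction, 25 / 140)
  expect_equal(comp$mismatched_fraction, 15 / 140)
  # loop-derived sequence is reported unclassified, not promoted
  expect_true(loop_seq %in% cat$unclassified$sequence)
  # partition: all mapped reads are either in a species or unclassified
  total_reads <- sum(tab$S01) + sum(tab$S02)
  expect_equal(sum(agg$counts) + sum(cat$unclassified$total_count),
               total_reads)
})

test_that("a miRNA species can be carried entirely by isomiRs", {
  ref <- simulate_reference(n_hairpins = 1L, genome_length = 3000L,
                            seed = 41L, single_mature_frac = 0)
  idx <- build_index(ref, k = 5L)
  h <- ref$hairpins[1, ]
  m5 <- ref$matures[ref$matures$arm == "5p", ][1, ]
  shifted <- substring(h$extended_sequence, m5$start + 1L, m5$end + 2L)
  tab <- list(S01 = stats::setNames(50L, shifted))
  mp <- map_unique_sequences(idx, shifted)
  cat <- call_expressed_species(ref, mp, tab)
  agg <- aggregate_counts(cat, tab)
  expect_equal(nrow(cat$species), 1L)
  expect_equal(agg$composition$exact_fraction, 0)
  # empty input gives an empty catalog and matrix
  cat0 <- call_expressed_species(ref,
                                 list(placements = list(),
                                      discarded = character(0),
                                      unmapped = character(0)),
                                 list(S01 = integer(0)))
  expect_equal(nrow(cat0$species), 0L)
  agg0 <- aggregate_counts(cat0, list(S01 = integer(0)))
  expect_equal(nrow(agg0$counts), 0L)
})

test_that("predicted sisters become new-miRNA species; duals are untouched", {
  ref <- tiny_ref()
  idx <- build_index(ref, k = 5L)
  sis <- ref$sisters_truth[1, ]
  h <- ref$hairpins[ref$hairpins$hairpin_id == sis$hairpin_id, ]
  sseq <- substring(h$extended_sequence, sis$start, sis$end)
  tab <- list(S01 = stats::setNames(40L, sseq))
  mp <- map_unique_sequences(idx, sseq)
  cat <- call_expressed_species(ref, mp, tab)
  expect_equal(cat$species$class, "new_miRNA")
  expect_equal(cat$species$species_id, paste0(sis$mature_name, "-sister"))
  # sister matures are only predicted for single-mature hairpins
  aug <- cat$matures
  dual_ids <- names(which(table(ref$matures$hairpin_id) == 2L))
  expect_false(any(aug$is_sister & aug$hairpin_id %in% dual_ids))
})
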