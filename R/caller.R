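#' Classify a hairpin placement
#'
#' Applies the class precedence exact miRNA > isomiR > moRNA > unclassified
#' to one placement on an extended hairpin:
#'
#' * exact: the interval equals a mature interval and the read has no
#'   mismatches;
#' * isomiR: both boundary shifts within +/-3 nt of some mature, with at most
#'   1 mismatch anywhere or 2 mismatches both in the 3' half of the read
#'   (positions strictly after `ceiling(len/2)`, 1-based); assigned to the
#'   mature minimizing |shift5| + |shift3|, ties to the 5p arm;
#' * moRNA: the central nucleotide (`start + floor((len - 1) / 2)`, the
#'   left-of-centre position for even lengths) lies strictly upstream of the
#'   5p mature region (moRNA_5p) or strictly downstream of the 3p mature
#'   region (moRNA_3p);
#' * otherwise unclassified (e.g. loop-derived).
#'
#' Predicted sister matures participate like annotated matures; exact/isomiR
#' assignments to a sister are reported with `on_sister = TRUE` so that the
#' catalog emits them as new miRNAs.
#'
#' @param start,end 1-based closed placement interval on the extended
#'   hairpin.
#' @param mismatch_positions integer vector of mismatched read positions
#'   (1-based on the read).
#' @param matures data.frame with columns name, arm ("5p"/"3p"), start, end
#'   and optionally is_sister.
#' @return list with `class` (miRNA_exact, isomiR, moRNA_5p, moRNA_3p or
#'   unclassified), `mature`, `shift5`, `shift3`, `central`, `on_sister`.
#' @export
classify_placement <- function(start, end, mismatch_positions, matures) {
  len <- end - start + 1L
  nmm <- length(mismatch_positions)
  central <- start + (len - 1L) %/% 2L
  res <- list(class = "unclassified", mature = NA_character_,
              shift5 = NA_integer_, shift3 = NA_integer_,
              central = central, on_sister = FALSE)
  if (is.null(matures) || !nrow(matures)) return(res)
  if (is.null(matures$is_sister)) matures$is_sister <- FALSE

  if (nmm == 0L) {
    hit <- which(matures$start == start & matures$end == end)
    if (length(hit)) {
      m <- matures[hit[1L], ]
      res$class <- "miRNA_exact"; res$mature <- m$name
      res$shift5 <- 0L; res$shift3 <- 0L; res$on_sister <- m$is_sister
      return(res)
    }
  }

  mm_ok <- nmm <= 1L ||
    (nmm == 2L && all(mismatch_positions > ceiling(len / 2)))
  if (mm_ok) {
    s5 <- start - matures$start
    s3 <- end - matures$end
    cand <- which(abs(s5) <= 3L & abs(s3) <= 3L)
    if (length(cand)) {
      tot <- abs(s5[cand]) + abs(s3[cand])
      pref <- order(tot, matures$arm[cand] != "5p", cand)
      b <- cand[pref[1L]]
      m <- matures[b, ]
      res$class <- "isomiR"; res$mature <- m$name
      res$shift5 <- s5[b]; res$shift3 <- s3[b]; res$on_sister <- m$is_sister
      return(res)
    }
  }

  m5 <- matures[matures$arm == "5p", , drop = FALSE]
  m3 <- matures[matures$arm == "3p", , drop = FALSE]
  if (nrow(m5) && central < min(m5$start)) {
    res$class <- "moRNA_5p"
    return(res)
  }
  if (nrow(m3) && central > max(m3$end)) {
    res$class <- "moRNA_3p"
    return(res)
  }
  res
}

#' Predict the sister mature from hairpin structure
#'
#' For a hairpin carrying a single annotated mature, uses the predicted
#' secondary structure to locate the region pairing with the mature and
#' returns the canonical duplex partner: the paired region adjusted to the
#' 2-nt 3' overhang convention of Dicer duplexes. Returns NULL when fewer
#' than `min_paired_frac` of the mature's bases are paired.
#'
#' @param extended_seq extended hairpin sequence.
#' @param mature_start,mature_end 1-based closed mature interval on the
#'   extended hairpin.
#' @param fold a `fold_result` for `extended_seq`, as from [fold_hairpin()];
#'   computed if NULL.
#' @param min_paired_frac minimum paired fraction of the mature (default
#'   0.6).
#' @return list with `start`, `end`, `arm` of the predicted sister, or NULL.
#' @export
discover_sister <- function(extended_seq, mature_start, mature_end,
                            fold = NULL, min_paired_frac = 0.6) {
  n <- nchar(extended_seq)
  if (mature_start < 1L || mature_end > n || mature_start >= mature_end)
    stop("mature interval outside the hairpin")
  if (is.null(fold)) fold <- fold_hairpin(extended_seq)
  partner <- rep(NA_integer_, n)
  if (nrow(fold$pairs)) {
    partner[fold$pairs[, 1L]] <- fold$pairs[, 2L]
    partner[fold$pairs[, 2L]] <- fold$pairs[, 1L]
  }
  mpos <- mature_start:mature_end
  paired <- mpos[!is.na(partner[mpos])]
  if (length(paired) < min_paired_frac * length(mpos)) return(NULL)
  pm5 <- partner[min(paired)]
  pm3 <- partner[max(paired)]
  s_start <- min(pm5, pm3) + 2L
  s_end <- max(pm5, pm3) + 2L
  s_start <- max(1L, s_start); s_end <- min(n, s_end)
  arm <- if (s_start > mature_end) "3p" else "5p"
  list(start = s_start, end = s_end, arm = arm)
}

# fold single-mature hairpins and append predicted sister matures
.augment_sisters <- function(ref) {
  mats <- ref$matures
  mats$is_sister <- FALSE
  per_hp <- split(seq_len(nrow(mats)), mats$hairpin_id)
  add <- list()
  for (hid in names(per_hp)) {
    rows <- per_hp[[hid]]
    if (length(rows) != 1L) next
    m <- mats[rows, ]
    ext <- ref$hairpins$extended_sequence[
      match(hid, ref$hairpins$hairpin_id)]
    sis <- tryCatch(discover_sister(ext, m$start, m$end), error = function(e) NULL)
    if (is.null(sis)) next
    add[[length(add) + 1L]] <- data.frame(
      hairpin_id = hid, family = m$family,
      name = paste0(m$name, "-sister"),
      arm = sis$arm, start = sis$start, end = sis$end, is_sister = TRUE,
      stringsAsFactors = FALSE)
  }
  if (length(add)) mats <- rbind(mats, do.call(rbind, add))
  mats
}

#' Build the expressed-species catalog
#'
#' Discovers sister matures on single-mature hairpins, classifies every
#' retained hairpin-mapped unique sequence, and emits one species per
#' annotated mature (exact + isomiR members), per expressed predicted sister
#' (new miRNA), and per moRNA region (named `moR-<family>-5p/3p`). Multi-copy
#' precursor families are counted once at the family level. A species is
#' emitted when detected in at least `min_samples` samples.
#'
#' @param ref an `srna_reference` (or compatible reference bundle).
#' @param mapres result of [map_unique_sequences()].
#' @param tables named list (per sample) of `unique_seq_table` objects (or
#'   plain named count vectors).
#' @param min_samples minimum number of samples in which a species must be
#'   detected (default 1).
#' @return object of class `species_catalog`: list with `species`
#'   (data.frame: species_id, class, family, hairpin_id, start, end,
#'   representative_sequence, n_members, n_samples_detected), `assignments`
#'   (data.frame: one row per classified sequence), `matures` (annotated plus
#'   predicted sister matures), `unclassified` (data.frame of unclassified or
#'   undetected sequences with their total read counts), and `samples`.
#' @export
call_expressed_species <- function(ref, mapres, tables, min_samples = 1L) {
  mats_all <- .augment_sisters(ref)
  samples <- names(tables)
  ctabs <- lapply(tables, function(tb)
    if (inherits(tb, "unique_seq_table")) tb$counts else tb)
  seqs <- names(mapres$placements)
  sc <- matrix(0L, length(seqs), length(samples),
               dimnames = list(seqs, samples))
  for (j in seq_along(samples)) {
    v <- ctabs[[j]][seqs]
    v[is.na(v)] <- 0L
    sc[, j] <- v
  }

  fam_of_hp <- stats::setNames(ref$hairpins$family, ref$hairpins$hairpin_id)
  rows <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    hp <- mapres$placements[[s]]
    hp <- hp[order(hp$mismatches, hp$reference_id, hp$start), , drop = FALSE]
    p <- hp[1L, ]
    mm_pos <- if (nzchar(p$mismatch_positions))
      as.integer(strsplit(p$mismatch_positions, ",", fixed = TRUE)[[1L]])
    else integer(0)
    mt <- mats_all[mats_all$hairpin_id == p$reference_id, , drop = FALSE]
    cl <- classify_placement(p$start, p$end, mm_pos, mt)
    fam <- unname(fam_of_hp[p$reference_id])
    species_id <- switch(cl$class,
      miRNA_exact = cl$mature, isomiR = cl$mature,
      moRNA_5p = paste0("moR-", sub("^mir-?", "", fam), "-5p"),
      moRNA_3p = paste0("moR-", sub("^mir-?", "", fam), "-3p"),
      NA_character_)
    species_class <- switch(cl$class,
      miRNA_exact = if (isTRUE(cl$on_sister)) "new_miRNA" else "miRNA",
      isomiR = if (isTRUE(cl$on_sister)) "new_miRNA" else "miRNA",
      moRNA_5p = "moRNA_5p", moRNA_3p = "moRNA_3p", "unclassified")
    variant <- if (cl$class == "miRNA_exact") "exact"
      else if (cl$class == "isomiR" && !length(mm_pos)) "shifted"
      else if (cl$class == "isomiR") "mismatched" else NA_character_
    rows[[i]] <- data.frame(
      sequence = s, hairpin_id = p$reference_id, family = fam,
      start = p$start, end = p$end, class = cl$class,
      species_class = species_class, species_id = species_id,
      mature = cl$mature, shift5 = cl$shift5, shift3 = cl$shift3,
      n_mismatch = length(mm_pos), variant = variant, central = cl$central,
      total_count = sum(sc[i, ]), stringsAsFactors = FALSE)
  }
  asg <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sequence = character(0), hairpin_id = character(0),
               family = character(0), start = integer(0), end = integer(0),
               class = character(0), species_class = character(0),
               species_id = character(0), mature = character(0),
               shift5 = integer(0), shift3 = integer(0),
               n_mismatch = integer(0), variant = character(0),
               central = integer(0), total_count = integer(0))

  cls <- asg[asg$species_class != "unclassified", , drop = FALSE]
  species <- data.frame()
  detected <- character(0)
  if (nrow(cls)) {
    spl <- split(seq_len(nrow(cls)), cls$species_id)
    sp_rows <- lapply(names(spl), function(sp) {
      r <- spl[[sp]]
      sub <- cls[r, ]
      smat <- sc[sub$sequence, , drop = FALSE]
      nsdet <- sum(colSums(smat) > 0L)
      rep_i <- which.max(rowSums(smat))
      # the species interval: the mature interval for (new) miRNAs, the
      # top member's interval for moRNAs
      if (sub$species_class[1L] %in% c("miRNA", "new_miRNA")) {
        m <- mats_all[mats_all$name == sub$mature[1L], ][1L, ]
        iv <- c(m$start, m$end)
      } else iv <- c(sub$start[rep_i], sub$end[rep_i])
      data.frame(species_id = sp, class = sub$species_class[1L],
                 family = sub$family[1L], hairpin_id = sub$hairpin_id[1L],
                 start = iv[1L], end = iv[2L],
                 representative_sequence = sub$sequence[rep_i],
                 n_members = nrow(sub), n_samples_detected = nsdet,
                 stringsAsFactors = FALSE)
    })
    species <- do.call(rbind, sp_rows)
    keep <- species$n_samples_detected >= min_samples
    detected <- species$species_id[keep]
    species <- species[keep, , drop = FALSE]
    species <- species[order(species$species_id), , drop = FALSE]
    rownames(species) <- NULL
  }

  uncl <- asg[asg$species_class == "unclassified" |
                !(asg$species_id %in% detected), , drop = FALSE]
  structure(list(species = species, assignments = asg, matures = mats_all,
                 unclassified = uncl[, c("sequence", "hairpin_id", "start",
                                         "end", "class", "total_count")],
                 samples = samples),
            class = "species_catalog")
}

#' @export
print.species_catalog <- function(x, ...) {
  cat("species_catalog:", nrow(x$species), "species\n")
  if (nrow(x$species)) print(table(x$species$class))
  invisible(x)
}

#' Aggregate per-species counts and isomiR composition
#'
#' The signal of each miRNA species is the sum of its exact sequence plus all
#' isomiR member sequences; new miRNAs and moRNAs are summed over their
#' members likewise. The isomiR detail table reports each member's variant
#' type (exact, shifted without mismatch, or mismatched) and the per-species
#' composition fractions.
#'
#' @param catalog a `species_catalog`.
#' @param tables named per-sample list of `unique_seq_table` objects (or
#'   named count vectors), the same used to build the catalog.
#' @return list with `counts` (species x samples matrix), `isomir_detail`
#'   (data.frame: species_id, sequence, variant, shift5, shift3, n_mismatch,
#'   per-sample counts), and `composition` (per species: exact_fraction,
#'   shifted_fraction, mismatched_fraction of total read counts).
#' @export
aggregate_counts <- function(catalog, tables) {
  stopifnot(inherits(catalog, "species_catalog"))
  samples <- names(tables)
  ctabs <- lapply(tables, function(tb)
    if (inherits(tb, "unique_seq_table")) tb$counts else tb)
  sp <- catalog$species
  asg <- catalog$assignments
  members <- asg[!is.na(asg$species_id) &
                   asg$species_id %in% sp$species_id, , drop = FALSE]
  if (nrow(members)) {
    mm <- matrix(0L, nrow(members), length(samples),
                 dimnames = list(NULL, samples))
    for (j in seq_along(samples)) {
      v <- ctabs[[j]][members$sequence]
      v[is.na(v)] <- 0L
      mm[, j] <- v
    }
    if (any(rowSums(mm) == 0L & !(members$sequence %in%
                                  unlist(lapply(ctabs, names)))))
      stop("catalog member sequence missing from every sample table")
    counts <- rowsum(mm, members$species_id)
    counts <- counts[sp$species_id, , drop = FALSE]
  } else {
    counts <- matrix(0L, 0L, length(samples),
                     dimnames = list(NULL, samples))
  }

  mir <- members[members$species_class %in% c("miRNA", "new_miRNA"), ,
                 drop = FALSE]
  detail <- data.frame()
  comp <- data.frame()
  if (nrow(mir)) {
    dmat <- matrix(0L, nrow(mir), length(samples),
                   dimnames = list(NULL, samples))
    for (j in seq_along(samples)) {
      v <- ctabs[[j]][mir$sequence]
      v[is.na(v)] <- 0L
      dmat[, j] <- v
    }
    detail <- cbind(mir[, c("species_id", "sequence", "variant", "shift5",
                            "shift3", "n_mismatch")], as.data.frame(dmat))
    rownames(detail) <- NULL
    tot <- rowSums(dmat)
    agg <- function(v) rowsum(tot * v, mir$species_id)
    by_sp <- rowsum(tot, mir$species_id)
    comp <- data.frame(
      species_id = rownames(by_sp),
      total = as.numeric(by_sp),
      exact_fraction = as.numeric(agg(mir$variant == "exact") / by_sp),
      shifted_fraction = as.numeric(agg(mir$variant == "shifted") / by_sp),
      mismatched_fraction = as.numeric(agg(mir$variant == "mismatched") /
                                         by_sp),
      stringsAsFactors = FALSE)
    rownames(comp) <- NULL
  }
  list(counts = counts, isomir_detail = detail, composition = comp)
}
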