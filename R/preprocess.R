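#' Trim the 3' adapter from one read
#'
#' Scans for the leftmost adapter occurrence: either the full adapter
#' anywhere in the read, or a prefix of the adapter overlapping the read end
#' by at least `min_overlap` nt, allowing up to
#' `floor(max_mismatch_rate * overlap)` mismatches. The insert is everything
#' before the match; qualities are trimmed in lockstep. An adapter match at
#' the first position rejects the read as `adapter_only`; no match rejects it
#' as `unclipped`.
#'
#' @param sequence read sequence (A/C/G/T/N).
#' @param qualities integer Phred scores, same length as the read.
#' @param adapter adapter sequence (non-empty, A/C/G/T).
#' @param min_overlap minimum 3'-end overlap (>= 3).
#' @param max_mismatch_rate allowed mismatch fraction of the aligned length.
#' @return list with `status` ("trimmed", "adapter_only" or "unclipped") and,
#'   when trimmed, `sequence` and `qualities` of the insert and `adapter_start`
#'   (1-based position of the match).
#' @export
trim_adapter <- function(sequence, qualities, adapter, min_overlap = 3L,
                         max_mismatch_rate = 0.1) {
  stopifnot(nchar(adapter) > 0L, min_overlap >= 3L)
  if (!grepl("^[ACGTN]*$", sequence))
    stop("read contains characters outside A/C/G/T/N")
  len <- nchar(sequence)
  stopifnot(length(qualities) == len)
  sv <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  av <- strsplit(adapter, "", fixed = TRUE)[[1L]]
  alen <- length(av)
  for (p in seq_len(len)) {
    ov <- min(len - p + 1L, alen)
    if (ov < alen && ov < min_overlap) break  # overlaps only shrink from here
    mism <- sum(sv[p:(p + ov - 1L)] != av[seq_len(ov)])
    if (mism <= floor(max_mismatch_rate * ov)) {
      if (p == 1L) return(list(status = "adapter_only"))
      return(list(status = "trimmed",
                  sequence = substr(sequence, 1L, p - 1L),
                  qualities = qualities[seq_len(p - 1L)],
                  adapter_start = p))
    }
  }
  list(status = "unclipped")
}

#' Length and quality filter for a trimmed read
#'
#' A read passes when its length is within `[min_len, max_len]`, its mean
#' Phred quality is strictly greater than `mean_q`, and at most `max_low`
#' bases have quality below `low_q`. Failure reasons are reported with the
#' precedence length, mean quality, low-quality bases.
#'
#' @param sequence insert sequence.
#' @param qualities integer Phred scores.
#' @param min_len,max_len retained length range (defaults 15 and 30 nt).
#' @param mean_q strict lower bound on the mean quality (default 30).
#' @param low_q,max_low at most `max_low` bases below `low_q`
#'   (defaults: 2 bases under Q20).
#' @return "pass", or one of "too_short", "too_long", "mean_quality",
#'   "low_quality_bases".
#' @export
quality_length_filter <- function(sequence, qualities, min_len = 15L,
                                  max_len = 30L, mean_q = 30,
                                  low_q = 20, max_low = 2L) {
  len <- nchar(sequence)
  stopifnot(length(qualities) == len)
  if (len < min_len) return("too_short")
  if (len > max_len) return("too_long")
  if (!(mean(qualities) > mean_q)) return("mean_quality")
  if (sum(qualities < low_q) > max_low) return("low_quality_bases")
  "pass"
}

#' Collapse passing reads of one sample and remove ground noise
#'
#' Identical insert sequences are collapsed to (sequence, count) and unique
#' sequences seen fewer than `min_count` times are discarded as ground noise.
#'
#' @param sequences character vector of passing insert sequences from one
#'   sample.
#' @param min_count minimum per-sample count for a unique sequence to be
#'   retained (default 10).
#' @return list with `counts` (named integer vector, retained sequences),
#'   `noise_removed` (number of reads discarded with their low-count
#'   sequences) and `noise_unique` (number of unique sequences discarded).
#' @export
collapse_and_filter <- function(sequences, min_count = 10L) {
  if (!length(sequences)) {
    return(list(counts = integer(0), noise_removed = 0L, noise_unique = 0L))
  }
  tab <- table(sequences)
  keep <- tab >= min_count
  counts <- as.integer(tab[keep])
  names(counts) <- names(tab[keep])
  list(counts = counts[order(names(counts))],
       noise_removed = as.integer(sum(tab[!keep])),
       noise_unique = as.integer(sum(!keep)))
}

#' Preprocess one FASTQ file
#'
#' Vectorized per-sample pipeline: adapter trimming (same rule as
#' [trim_adapter()]), length/quality filtering (as
#' [quality_length_filter()]), collapsing to unique sequences and removal of
#' low-count ground noise. Read accounting is conserved: every input read is
#' attributed to exactly one of the rejection reasons, the noise bin, or the
#' retained table.
#'
#' @param fastq path to a Phred+33 FASTQ file.
#' @param adapter 3' adapter sequence.
#' @param min_overlap,max_mismatch_rate see [trim_adapter()].
#' @param min_len,max_len,mean_q,low_q,max_low see [quality_length_filter()].
#' @param min_count see [collapse_and_filter()].
#' @return object of class `unique_seq_table`: list with `counts` (named
#'   integer vector sequence -> count) and `stats` (named integer vector of
#'   the filter accounting).
#' @export
preprocess_fastq <- function(fastq, adapter = "TGGAATTCTCGGGTGCCAAGG",
                             min_overlap = 3L, max_mismatch_rate = 0.1,
                             min_len = 15L, max_len = 30L, mean_q = 30,
                             low_q = 20, max_low = 2L, min_count = 10L) {
  seqs <- Biostrings::readDNAStringSet(fastq, format = "fastq",
                                       with.qualities = TRUE)
  quals <- Biostrings::PhredQuality(S4Vectors::mcols(seqs)$qualities)
  qints <- methods::as(quals, "IntegerList")
  n <- length(seqs)
  widths <- Biostrings::width(seqs)
  alen <- nchar(adapter)

  # leftmost full internal adapter match
  adapter_pos <- rep(NA_integer_, n)
  full <- Biostrings::vmatchPattern(adapter, seqs,
                                    max.mismatch = floor(max_mismatch_rate * alen),
                                    with.indels = FALSE)
  stl <- Biostrings::startIndex(full)
  l <- lengths(stl)
  flat <- as.integer(unlist(stl, use.names = FALSE))
  grp0 <- rep.int(seq_len(n), l)
  # vmatchPattern also reports shifted matches overhanging the read ends
  # (overhang counted as mismatches); keep fully in-bounds matches only
  inb <- flat >= 1L & flat <= widths[grp0] - alen + 1L
  flat <- flat[inb]; grp0 <- grp0[inb]
  o <- order(grp0, flat)
  firstpos <- !duplicated(grp0[o])
  adapter_pos[grp0[o][firstpos]] <- flat[o][firstpos]

  # 3'-end partial overlaps, longest (leftmost) first, anchored at the
  # read end
  pend <- which(is.na(adapter_pos))
  avec <- strsplit(adapter, "", fixed = TRUE)[[1L]]
  if (length(pend) && alen - 1L >= min_overlap) {
    for (ov in seq(alen - 1L, min_overlap)) {
      if (!length(pend)) break
      cand <- pend[widths[pend] >= ov]
      if (!length(cand)) next
      tails <- as.character(Biostrings::subseq(
        seqs[cand], start = widths[cand] - ov + 1L, end = widths[cand]))
      tm <- matrix(unlist(strsplit(tails, "", fixed = TRUE)),
                   ncol = ov, byrow = TRUE)
      nmm <- rowSums(tm != matrix(avec[seq_len(ov)], nrow(tm), ov,
                                  byrow = TRUE))
      hit <- nmm <= floor(max_mismatch_rate * ov)
      adapter_pos[cand[hit]] <- widths[cand[hit]] - ov + 1L
      pend <- setdiff(pend, cand[hit])
    }
  }

  status <- rep("unclipped", n)
  status[!is.na(adapter_pos) & adapter_pos == 1L] <- "adapter_only"
  trimmed <- !is.na(adapter_pos) & adapter_pos > 1L
  status[trimmed] <- "trimmed"

  ins_len <- integer(n)
  ins_len[trimmed] <- adapter_pos[trimmed] - 1L
  reason <- rep(NA_character_, n)
  idx <- which(trimmed)
  if (length(idx)) {
    qsub <- qints[idx]
    ends <- ins_len[idx]
    qv <- unlist(qsub, use.names = FALSE)
    pos_in_read <- sequence(widths[idx])
    keep_q <- pos_in_read <= rep(ends, widths[idx])
    grp <- rep(seq_along(idx), widths[idx])[keep_q]
    qv <- qv[keep_q]
    qsum <- rowsum(qv, grp)[, 1L]
    qlow <- rowsum((qv < low_q) * 1L, grp)[, 1L]
    lensub <- ends
    r <- rep("pass", length(idx))
    r[lensub > max_len] <- "too_long"
    r[lensub < min_len] <- "too_short"
    mid <- r == "pass"
    r[mid & !(qsum / lensub > mean_q)] <- "mean_quality"
    mid <- r == "pass"
    r[mid & qlow > max_low] <- "low_quality_bases"
    reason[idx] <- r
  }

  passing <- which(trimmed & reason == "pass")
  inserts <- substr(as.character(seqs[passing]), 1L, ins_len[passing])
  cf <- collapse_and_filter(unname(inserts), min_count)

  stats <- c(reads_in = n,
             adapter_only = sum(status == "adapter_only"),
             unclipped = sum(status == "unclipped"),
             too_short = sum(reason == "too_short", na.rm = TRUE),
             too_long = sum(reason == "too_long", na.rm = TRUE),
             mean_quality = sum(reason == "mean_quality", na.rm = TRUE),
             low_quality_bases = sum(reason == "low_quality_bases",
                                     na.rm = TRUE),
             noise_removed = cf$noise_removed,
             retained_reads = sum(cf$counts),
             retained_unique = length(cf$counts))
  structure(list(counts = cf$counts, stats = stats),
            class = "unique_seq_table")
}

#' @export
print.unique_seq_table <- function(x, ...) {
  cat(sprintf("unique_seq_table: %d retained sequences (%d reads)\n",
              length(x$counts), sum(x$counts)))
  print(x$stats)
  invisible(x)
}
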