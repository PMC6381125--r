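#' Scan a transcript for putative moRNA target sites
#'
#' Slides a window of `nchar(morna) + slack` nt along the transcript and
#' folds the moRNA against each window with [duplex_fold()]. A window is a
#' hit when (i) some contiguous block of `seed_len` moRNA positions is fully
#' paired with consecutive target positions (no unpaired base, no bulge) with
#' at most `max_seed_wobble` G:U pairs, the block lying within the moRNA's
#' 5' seed region; (ii) the duplex has at least `min_pairs` base pairs (G:U
#' counted); and (iii) its free energy is at most `max_energy` kcal/mol.
#' Overlapping hit windows are merged, keeping the lowest-energy hit.
#'
#' @param morna moRNA sequence, 15-35 nt (A/C/G/T/U).
#' @param transcript target transcript sequence (A/C/G/T/U/N; windows
#'   containing N are skipped).
#' @param seed_len seed block length (default 7).
#' @param max_seed_wobble maximum G:U pairs tolerated inside the seed block
#'   (default 1).
#' @param min_pairs minimum total base pairs in the heteroduplex (default
#'   14).
#' @param max_energy maximum (most positive) allowed duplex free energy in
#'   kcal/mol (default -20).
#' @param seed_region 1-based inclusive interval of moRNA positions the seed
#'   block must lie in (default `c(1, 10)`, the 5' 10 nt); NULL allows the
#'   whole moRNA.
#' @param slack extra window width beyond the moRNA length (default 6).
#' @return data.frame of target hits: start, end (window on the transcript,
#'   1-based closed), total_pairs, wobble_count, wobbles_in_seed, energy.
#' @export
scan_transcript <- function(morna, transcript, seed_len = 7L,
                            max_seed_wobble = 1L, min_pairs = 14L,
                            max_energy = -20, seed_region = c(1L, 10L),
                            slack = 6L) {
  mlen <- nchar(morna)
  if (mlen < 15L || mlen > 35L)
    stop("moRNA length must be within 15-35 nt")
  if (!grepl("^[ACGTUacgtu]+$", morna))
    stop("moRNA contains invalid characters")
  if (!grepl("^[ACGTUNacgtun]+$", transcript))
    stop("transcript contains characters outside A/C/G/T/U/N")
  L <- nchar(transcript)
  w <- min(mlen + slack, L)
  if (L < seed_len) stop("transcript shorter than the seed window")
  starts <- seq_len(L - w + 1L)
  hits <- list()
  for (s in starts) {
    win <- substr(transcript, s, s + w - 1L)
    if (grepl("N", win, fixed = TRUE)) next
    d <- duplex_fold(morna, win)
    np <- nrow(d$pairs)
    if (np < min_pairs || d$energy > max_energy) next
    seed <- .seed_block_check(d, morna, seed_len, max_seed_wobble,
                              seed_region)
    if (is.null(seed)) next
    hits[[length(hits) + 1L]] <- data.frame(
      start = s, end = s + w - 1L, total_pairs = np,
      wobble_count = d$wobble_count, wobbles_in_seed = seed,
      energy = d$energy)
  }
  if (!length(hits)) {
    return(data.frame(start = integer(0), end = integer(0),
                      total_pairs = integer(0), wobble_count = integer(0),
                      wobbles_in_seed = integer(0), energy = numeric(0)))
  }
  df <- do.call(rbind, hits)
  .merge_hits(df)
}

# lowest G:U count over qualifying fully stacked seed blocks, or NULL
.seed_block_check <- function(d, morna, seed_len, max_seed_wobble,
                              seed_region) {
  if (!nrow(d$pairs)) return(NULL)
  a <- encode_bases(morna, allow_n = TRUE)
  b <- encode_bases(d$target, allow_n = TRUE)
  em <- energy_model()
  # runs of consecutive pairs: adjacent on the moRNA and on the target
  ord <- order(d$pairs[, 1L])
  pr <- d$pairs[ord, , drop = FALSE]
  runs <- .contiguous_runs(cbind(pr[, 1L], -pr[, 2L]))
  best <- NULL
  for (run in runs) {
    if (length(run) < seed_len) next
    apos <- pr[run, 1L]
    bpos <- pr[run, 2L]
    for (o in seq_len(length(run) - seed_len + 1L)) {
      ai <- apos[o:(o + seed_len - 1L)]
      if (!is.null(seed_region) &&
          (min(ai) < seed_region[1L] || max(ai) > seed_region[2L])) next
      wob <- sum(em$wobble[cbind(a[ai], b[bpos[o:(o + seed_len - 1L)]])])
      if (wob <= max_seed_wobble && (is.null(best) || wob < best))
        best <- wob
    }
  }
  best
}

# merge overlapping windows, keeping the lowest-energy hit per cluster
.merge_hits <- function(df) {
  df <- df[order(df$start, df$end), , drop = FALSE]
  cluster <- integer(nrow(df))
  cur <- 1L; cur_end <- df$end[1L]; cluster[1L] <- 1L
  for (i in seq_len(nrow(df))[-1L]) {
    if (df$start[i] <= cur_end) {
      cluster[i] <- cur
      cur_end <- max(cur_end, df$end[i])
    } else {
      cur <- cur + 1L
      cluster[i] <- cur
      cur_end <- df$end[i]
    }
  }
  picks <- vapply(split(seq_len(nrow(df)), cluster), function(ix) {
    ix[order(df$energy[ix], df$start[ix])][1L]
  }, integer(1L))
  out <- df[sort(picks), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan many moRNAs against many transcripts
#'
#' Convenience wrapper over [scan_transcript()].
#'
#' @param mornas named character vector of moRNA sequences.
#' @param transcripts named character vector of transcript sequences (e.g.
#'   read with `Biostrings::readDNAStringSet`).
#' @param ... parameters passed to [scan_transcript()].
#' @return data.frame with columns morna, transcript and the
#'   [scan_transcript()] hit columns.
#' @export
scan_targets <- function(mornas, transcripts, ...) {
  out <- list()
  for (m in names(mornas)) {
    for (tr in names(transcripts)) {
      h <- scan_transcript(mornas[[m]], transcripts[[tr]], ...)
      if (nrow(h)) {
        out[[length(out) + 1L]] <- cbind(morna = m, transcript = tr, h,
                                         stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(morna = character(0), transcript = character(0),
                      start = integer(0), end = integer(0),
                      total_pairs = integer(0), wobble_count = integer(0),
                      wobbles_in_seed = integer(0), energy = numeric(0)))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
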