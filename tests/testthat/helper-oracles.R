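# Independent brute-force re-implementations used as oracles. These are kept
# deliberately naive (direct transcription of the rules) and share no code
# with the package internals they check.

# --- read filtering -------------------------------------------------------

oracle_trim <- function(sequence, adapter, min_overlap = 3L,
                        max_mismatch_rate = 0.1) {
  sv <- strsplit(sequence, "")[[1]]
  av <- strsplit(adapter, "")[[1]]
  len <- length(sv); alen <- length(av)
  for (p in seq_len(len)) {
    ov <- min(len - p + 1L, alen)
    full <- ov == alen
    if (!full && ov < min_overlap) next
    mm <- sum(sv[p + seq_len(ov) - 1L] != av[seq_len(ov)])
    if (mm <= floor(max_mismatch_rate * ov)) {
      if (p == 1L) return(list(status = "adapter_only"))
      return(list(status = "trimmed", insert_len = p - 1L))
    }
  }
  list(status = "unclipped")
}

oracle_qualfilter <- function(len, quals, min_len = 15L, max_len = 30L,
                              mean_q = 30, low_q = 20, max_low = 2L) {
  q <- quals[seq_len(len)]
  if (len < min_len) "too_short"
  else if (len > max_len) "too_long"
  else if (sum(q) / len <= mean_q) "mean_quality"
  else if (length(which(q < low_q)) > max_low) "low_quality_bases"
  else "pass"
}

# full per-read filtering decision (trim + quality/length), as one rule list
oracle_read_decision <- function(sequence, quals, adapter, ...) {
  tr <- oracle_trim(sequence, adapter)
  if (tr$status != "trimmed") return(tr$status)
  oracle_qualfilter(tr$insert_len, quals)
}

# --- classification -------------------------------------------------------

# direct transcription of the precedence rules; 1-based closed intervals
oracle_classify <- function(start, end, mm_pos, matures) {
  len <- end - start + 1L
  if (is.null(matures$is_sister)) matures$is_sister <- FALSE
  if (length(mm_pos) == 0L) {
    for (i in seq_len(nrow(matures))) {
      if (matures$start[i] == start && matures$end[i] == end)
        return(list(class = "miRNA_exact", mature = matures$name[i]))
    }
  }
  half <- ceiling(len / 2)
  mm_ok <- length(mm_pos) == 0L || length(mm_pos) == 1L ||
    (length(mm_pos) == 2L && mm_pos[1] > half && mm_pos[2] > half)
  if (mm_ok) {
    best <- NULL
    for (i in seq_len(nrow(matures))) {
      s5 <- start - matures$start[i]; s3 <- end - matures$end[i]
      if (abs(s5) > 3L || abs(s3) > 3L) next
      score <- abs(s5) + abs(s3)
      pri <- if (matures$arm[i] == "5p") 0L else 1L
      key <- c(score, pri, i)
      if (is.null(best) ||
          (key[1] < best$key[1]) ||
          (key[1] == best$key[1] && key[2] < best$key[2]) ||
          (key[1] == best$key[1] && key[2] == best$key[2] &&
             key[3] < best$key[3]))
        best <- list(key = key, i = i)
    }
    if (!is.null(best))
      return(list(class = "isomiR", mature = matures$name[best$i]))
  }
  centre <- start + floor((len - 1) / 2)
  m5 <- matures[matures$arm == "5p", , drop = FALSE]
  m3 <- matures[matures$arm == "3p", , drop = FALSE]
  if (nrow(m5) > 0 && centre < min(m5$start))
    return(list(class = "moRNA_5p", mature = NA))
  if (nrow(m3) > 0 && centre > max(m3$end))
    return(list(class = "moRNA_3p", mature = NA))
  list(class = "unclassified", mature = NA)
}

# --- folding --------------------------------------------------------------

# independent energy-model lookup built directly from the shipped table
.oracle_energy <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    path <- system.file("extdata", "stack_energies.tsv", package = "moRseq")
    tab <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE)
    init <- tab$dG[tab$motif == "INIT"]
    tab <- tab[tab$motif != "INIT", ]
    vals <- c(stats::setNames(tab$dG, tab$motif),
              stats::setNames(tab$dG, paste0(
                substr(tab$motif, 5, 5), substr(tab$motif, 4, 4), "/",
                substr(tab$motif, 2, 2), substr(tab$motif, 1, 1))))
    vals <- vals[!duplicated(names(vals))]
    cache <<- list(vals = vals, init = init)
    cache
  }
})

.oracle_can_pair <- function(x, y) {
  paste0(x, y) %in% c("AU", "UA", "CG", "GC", "GU", "UG")
}

# score a pair set: stack term when the inward neighbour is paired, helix
# initiation otherwise
oracle_structure_energy <- function(seq, pairs) {
  em <- .oracle_energy()
  if (!nrow(pairs)) return(0)
  v <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  keyset <- paste(pairs[, 1], pairs[, 2])
  e <- 0
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (paste(i + 1, j - 1) %in% keyset) {
      motif <- paste0(v[i], v[i + 1], "/", v[j], v[j - 1])
      e <- e + em$vals[[motif]]
    } else e <- e + em$init
  }
  e
}

# enumerate every nested structure of a short sequence, return the minimum
# energy (and the count of structures visited)
oracle_enumerate_fold <- function(seq, min_loop = 3L) {
  v <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  n <- length(v)
  best <- 0  # the empty structure
  structs <- function(i, j) {
    # list of pair matrices for region [i, j]
    if (j - i < min_loop + 1L) return(list(matrix(numeric(0), 0, 2)))
    out <- structs(i + 1L, j)  # i unpaired
    for (k in (i + min_loop + 1L):j) {
      if (!.oracle_can_pair(v[i], v[k])) next
      left <- structs(i + 1L, k - 1L)
      right <- if (k + 1L <= j) structs(k + 1L, j)
               else list(matrix(numeric(0), 0, 2))
      for (a in left) for (b in right)
        out[[length(out) + 1L]] <- rbind(c(i, k), a, b)
    }
    out
  }
  all <- structs(1L, n)
  for (s in all) {
    e <- oracle_structure_energy(seq, s)
    if (e < best) best <- e
  }
  list(energy = best, n_structures = length(all))
}

# --- mapping --------------------------------------------------------------

.oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# naive full scan over every offset and strand
oracle_map_genome <- function(genome, query, max_mm) {
  L <- nchar(genome); len <- nchar(query)
  out <- NULL
  for (strand in c("+", "-")) {
    q <- if (strand == "+") query else .oracle_revcomp(query)
    qv <- strsplit(q, "")[[1]]
    for (s in seq_len(L - len + 1L)) {
      rv <- strsplit(substr(genome, s, s + len - 1L), "")[[1]]
      if (sum(rv != qv) <= max_mm)
        out <- rbind(out, data.frame(start = s, end = s + len - 1L,
                                     strand = strand))
    }
  }
  out
}

# --- target scanning ------------------------------------------------------

# full-window brute force: every window, constraints applied independently
# of the scanner's code path
oracle_scan <- function(morna, transcript, seed_len = 7L,
                        max_seed_wobble = 1L, min_pairs = 14L,
                        max_energy = -20, seed_region = c(1L, 10L),
                        slack = 6L) {
  L <- nchar(transcript); w <- min(nchar(morna) + slack, L)
  hits <- NULL
  for (s in seq_len(L - w + 1L)) {
    win <- substr(transcript, s, s + w - 1L)
    if (grepl("N", win, fixed = TRUE)) next
    d <- duplex_fold(morna, win)
    if (nrow(d$pairs) < min_pairs) next
    if (d$energy > max_energy) next
    # seed: any fully stacked block of seed_len with <= max_seed_wobble G:U
    pr <- d$pairs[order(d$pairs[, 1]), , drop = FALSE]
    mv <- strsplit(chartr("T", "U", toupper(morna)), "")[[1]]
    tv <- strsplit(chartr("T", "U", toupper(win)), "")[[1]]
    ok <- FALSE
    for (o in seq_len(nrow(pr) - seed_len + 1L)) {
      blk <- pr[o:(o + seed_len - 1L), , drop = FALSE]
      if (any(diff(blk[, 1]) != 1L) || any(diff(blk[, 2]) != -1L)) next
      if (!is.null(seed_region) &&
          (blk[1, 1] < seed_region[1] ||
             blk[seed_len, 1] > seed_region[2])) next
      wob <- sum(paste0(mv[blk[, 1]], tv[blk[, 2]]) %in% c("GU", "UG"))
      if (wob <= max_seed_wobble) { ok <- TRUE; break }
    }
    if (ok) hits <- rbind(hits, data.frame(start = s, end = s + w - 1L,
                                           energy = d$energy))
  }
  hits
}

# merged clusters of the oracle hit windows (lowest energy per cluster)
oracle_merge <- function(hits) {
  if (is.null(hits)) return(NULL)
  hits <- hits[order(hits$start), , drop = FALSE]
  out <- NULL; cs <- hits$start[1]; ce <- hits$end[1]; rows <- 1L
  flush <- function(rows) {
    sub <- hits[rows, , drop = FALSE]
    sub[order(sub$energy, sub$start), , drop = FALSE][1, ]
  }
  for (i in seq_len(nrow(hits))[-1]) {
    if (hits$start[i] <= ce) { ce <- max(ce, hits$end[i]); rows <- c(rows, i) }
    else { out <- rbind(out, flush(rows)); cs <- hits$start[i]
           ce <- hits$end[i]; rows <- i }
  }
  rbind(out, flush(rows))
}
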