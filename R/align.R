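#' Build an exact k-mer seed index over genome and extended hairpins
#'
#' Indexes every k-mer of the genome (plus strand) and of each extended
#' hairpin sequence. Queries are mapped seed-and-verify: a query with at most
#' m substitutions must contain an exactly matching segment of length
#' `floor(len / (m + 1))` (pigeonhole), so `k` must not exceed that for the
#' shortest query at the highest mismatch budget.
#'
#' @param ref an `srna_reference` (or any list with `genome`, `contig`,
#'   `hairpins` as produced by [simulate_reference()] / [read_reference()]).
#' @param k seed length (<= 15; default 5 supports 15-nt queries at 2
#'   mismatches).
#' @return object of class `seed_index`.
#' @export
build_index <- function(ref, k = 5L) {
  stopifnot(k >= 3L, k <= 15L)
  g <- ref$genome
  L <- nchar(g)
  starts <- seq_len(L - k + 1L)
  gdt <- data.table::data.table(kmer = substring(g, starts, starts + k - 1L),
                                pos = starts)
  data.table::setkey(gdt, kmer)
  hp <- ref$hairpins
  hlist <- lapply(seq_len(nrow(hp)), function(i) {
    s <- hp$extended_sequence[i]
    n <- nchar(s)
    if (n < k) return(NULL)
    st <- seq_len(n - k + 1L)
    data.table::data.table(kmer = substring(s, st, st + k - 1L),
                           ref_id = hp$hairpin_id[i], pos = st)
  })
  hdt <- data.table::rbindlist(hlist)
  if (!nrow(hdt))
    hdt <- data.table::data.table(kmer = character(0),
                                  ref_id = character(0), pos = integer(0))
  data.table::setkey(hdt, kmer)
  structure(list(k = k, genome = g, contig = ref$contig,
                 genome_index = gdt, hairpin_index = hdt,
                 hairpins = hp,
                 hairpin_seqs = stats::setNames(hp$extended_sequence,
                                                hp$hairpin_id),
                 hairpin_loci = data.frame(start = hp$start, end = hp$end)),
            class = "seed_index")
}

# count mismatches between a query and same-length reference substrings
.mismatch_rows <- function(query_vec, refs) {
  if (!length(refs)) return(list(n = integer(0), pos = list()))
  m <- matrix(unlist(strsplit(refs, "", fixed = TRUE)),
              nrow = length(refs), byrow = TRUE)
  neq <- m != matrix(query_vec, nrow = length(refs), ncol = length(query_vec),
                     byrow = TRUE)
  list(n = rowSums(neq),
       pos = apply(neq, 1L, which, simplify = FALSE))
}

# candidate start positions from pigeonhole seeds against one keyed table
.seed_candidates <- function(dt, query, k, max_mm, hairpin = FALSE) {
  len <- nchar(query)
  nseg <- max_mm + 1L
  seg_len <- len %/% nseg
  if (seg_len < k) stop("index k too large for query length ", len,
                        " at max_mismatches ", max_mm)
  offs <- (seq_len(nseg) - 1L) * seg_len + 1L
  res <- list()
  for (i in seq_along(offs)) {
    seed <- substring(query, offs[i], offs[i] + k - 1L)
    hit <- dt[data.table::data.table(kmer = seed), nomatch = NULL,
              on = "kmer"]
    if (!nrow(hit)) next
    res[[length(res) + 1L]] <- if (hairpin)
      data.table::data.table(ref_id = hit$ref_id,
                             start = hit$pos - offs[i] + 1L)
    else data.table::data.table(start = hit$pos - offs[i] + 1L)
  }
  if (!length(res)) return(NULL)
  as.data.frame(unique(data.table::rbindlist(res)))
}

#' Map one sequence to genome and extended hairpins
#'
#' Returns all ungapped placements with at most `max_mismatches`
#' substitutions: on both strands of the genome and on the forward strand of
#' every extended hairpin. Placements are ordered deterministically by
#' reference kind, reference id, start and strand.
#'
#' @param index a `seed_index`.
#' @param seq query sequence, 15-30 nt.
#' @param max_mismatches maximum substitutions.
#' @return data.frame with columns reference_kind ("hairpin"/"genome"),
#'   reference_id, start, end (1-based closed), strand, mismatches,
#'   mismatch_positions (comma-separated 1-based query positions).
#' @export
map_sequence <- function(index, seq, max_mismatches = 2L) {
  len <- nchar(seq)
  stopifnot(len >= 15L, len <= 30L)
  out <- list()
  qv_fwd <- strsplit(seq, "", fixed = TRUE)[[1L]]
  L <- nchar(index$genome)

  for (strand in c("+", "-")) {
    q <- if (strand == "+") seq else revcomp(seq)
    qv <- strsplit(q, "", fixed = TRUE)[[1L]]
    cand <- .seed_candidates(index$genome_index, q, index$k, max_mismatches)
    if (is.null(cand)) next
    st <- cand$start
    st <- st[st >= 1L & st + len - 1L <= L]
    if (!length(st)) next
    refs <- substring(index$genome, st, st + len - 1L)
    mm <- .mismatch_rows(qv, refs)
    keep <- which(mm$n <= max_mismatches)
    for (i in keep) {
      # mismatch positions reported in query coordinates
      mp <- mm$pos[[i]]
      if (strand == "-") mp <- sort(len - mp + 1L)
      out[[length(out) + 1L]] <- data.frame(
        reference_kind = "genome", reference_id = index$contig,
        start = st[i], end = st[i] + len - 1L, strand = strand,
        mismatches = mm$n[i],
        mismatch_positions = paste(mp, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }

  cand <- .seed_candidates(index$hairpin_index, seq, index$k, max_mismatches,
                           hairpin = TRUE)
  if (!is.null(cand) && nrow(cand)) {
    hw <- nchar(index$hairpin_seqs)[cand$ref_id]
    ok <- cand$start >= 1L & cand$start + len - 1L <= hw
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand)) {
      refs <- substring(index$hairpin_seqs[cand$ref_id], cand$start,
                        cand$start + len - 1L)
      mm <- .mismatch_rows(qv_fwd, refs)
      keep <- which(mm$n <= max_mismatches)
      for (i in keep) {
        out[[length(out) + 1L]] <- data.frame(
          reference_kind = "hairpin", reference_id = cand$ref_id[i],
          start = cand$start[i], end = cand$start[i] + len - 1L,
          strand = "+", mismatches = mm$n[i],
          mismatch_positions = paste(mm$pos[[i]], collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }

  if (!length(out)) {
    return(data.frame(reference_kind = character(0),
                      reference_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mismatches = integer(0),
                      mismatch_positions = character(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$reference_kind, res$reference_id, res$start, res$strand), ,
      drop = FALSE]
}

#' Multimapping noise filter
#'
#' Counts the distinct genome placements (contig, start, strand) whose
#' interval does not overlap any annotated hairpin locus; the sequence is
#' discarded when that count exceeds `max_extra_loci`.
#'
#' @param placements data.frame from [map_sequence()] (one query sequence).
#' @param hairpin_loci data.frame with `start`, `end` of hairpin loci.
#' @param max_extra_loci maximum tolerated extra-hairpin loci (default 5).
#' @return TRUE to keep the sequence, FALSE to discard it.
#' @export
apply_multimap_filter <- function(placements, hairpin_loci,
                                  max_extra_loci = 5L) {
  g <- placements[placements$reference_kind == "genome", , drop = FALSE]
  if (!nrow(g)) return(TRUE)
  g <- g[!duplicated(paste(g$reference_id, g$start, g$strand)), , drop = FALSE]
  if (nrow(hairpin_loci)) {
    ov <- IRanges::overlapsAny(
      IRanges::IRanges(g$start, g$end),
      IRanges::IRanges(hairpin_loci$start, hairpin_loci$end))
  } else ov <- rep(FALSE, nrow(g))
  sum(!ov) <= max_extra_loci
}

#' Write placements as BED
#'
#' Exports genome placements in BED format (0-based half-open intervals,
#' name = query sequence, score = mismatch count).
#'
#' @param placements data.frame from [map_sequence()] (any number of
#'   queries; rows with `reference_kind == "genome"` are written).
#' @param path output file.
#' @param name optional name column (defaults to the reference id).
#' @return invisibly, the path.
#' @export
placements_to_bed <- function(placements, path, name = NULL) {
  g <- placements[placements$reference_kind == "genome", , drop = FALSE]
  if (is.null(name)) name <- g$reference_id
  df <- data.frame(chrom = g$reference_id, start = g$start - 1L,
                   end = g$end, name = name, score = g$mismatches,
                   strand = g$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Map a table of unique sequences
#'
#' Applies [map_sequence()] and [apply_multimap_filter()] to every retained
#' unique sequence of a sample (or the union across samples).
#'
#' @param index a `seed_index`.
#' @param seqs character vector of unique sequences.
#' @param max_mismatches maximum substitutions per placement.
#' @param max_extra_loci multimap filter threshold.
#' @return list with `placements` (named list of data.frames, hairpin
#'   placements only, for sequences kept by the filter), `discarded`
#'   (character vector of multimapper sequences), `unmapped` (sequences with
#'   no hairpin placement).
#' @export
map_unique_sequences <- function(index, seqs, max_mismatches = 2L,
                                 max_extra_loci = 5L) {
  placements <- list()
  discarded <- character(0)
  unmapped <- character(0)
  for (s in seqs) {
    p <- map_sequence(index, s, max_mismatches)
    if (!apply_multimap_filter(p, index$hairpin_loci, max_extra_loci)) {
      discarded <- c(discarded, s)
      next
    }
    hp <- p[p$reference_kind == "hairpin", , drop = FALSE]
    if (!nrow(hp)) {
      unmapped <- c(unmapped, s)
      next
    }
    placements[[s]] <- hp
  }
  list(placements = placements, discarded = discarded, unmapped = unmapped)
}
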