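#' Write a simulated reference bundle to disk
#'
#' Writes the genome FASTA, the hairpin FASTA (precursor sequences), and a
#' miRBase-style GFF3 annotation with `miRNA_primary_transcript` features for
#' hairpins and `miRNA` features for annotated matures (1-based inclusive
#' genomic coordinates).
#'
#' @param ref an `srna_reference`.
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of written paths.
#' @export
write_reference <- function(ref, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gpath <- file.path(dir, "genome.fa")
  g <- Biostrings::DNAStringSet(stats::setNames(ref$genome, ref$contig))
  Biostrings::writeXStringSet(g, gpath)
  hpath <- file.path(dir, "hairpins.fa")
  h <- Biostrings::DNAStringSet(stats::setNames(ref$hairpins$sequence,
                                                ref$hairpins$hairpin_id))
  Biostrings::writeXStringSet(h, hpath)

  apath <- file.path(dir, "annotation.gff3")
  hp <- ref$hairpins
  mt <- ref$matures
  hp_g <- GenomicRanges::GRanges(
    seqnames = hp$contig,
    ranges = IRanges::IRanges(hp$start, hp$end), strand = hp$strand,
    type = "miRNA_primary_transcript", ID = hp$hairpin_id,
    Name = hp$hairpin_id, family = hp$family)
  off <- hp$ext_start[match(mt$hairpin_id, hp$hairpin_id)] - 1L
  mt_g <- GenomicRanges::GRanges(
    seqnames = hp$contig[match(mt$hairpin_id, hp$hairpin_id)],
    ranges = IRanges::IRanges(mt$start + off, mt$end + off), strand = "+",
    type = "miRNA", ID = paste0(mt$name, "@", mt$hairpin_id),
    Name = mt$name, family = mt$family, Derives_from = mt$hairpin_id)
  gff <- c(hp_g, mt_g)
  rtracklayer::export(gff, apath, format = "gff3")
  invisible(c(genome = gpath, hairpins = hpath, annotation = apath))
}

#' Read a reference bundle from genome FASTA and GFF3 annotation
#'
#' Reconstructs the hairpin + mature reference used by the pipeline from a
#' genome FASTA and a miRBase-style GFF3 (features
#' `miRNA_primary_transcript` and `miRNA` with `Derives_from` or positional
#' containment linking matures to hairpins). Hairpins are extended by
#' `flank` nt of genomic context and mature coordinates are converted to the
#' extended-hairpin frame.
#'
#' @param genome_fa path to the genome FASTA.
#' @param gff3 path to the annotation GFF3.
#' @param flank flank length (default 30).
#' @return an `srna_reference`-compatible object.
#' @export
read_reference <- function(genome_fa, gff3, flank = 30L) {
  gset <- Biostrings::readDNAStringSet(genome_fa)
  names(gset) <- sub("\\s.*$", "", names(gset))
  ann <- rtracklayer::import(gff3, format = "gff3")
  is_hp <- ann$type == "miRNA_primary_transcript"
  is_mat <- ann$type == "miRNA"
  hpg <- ann[is_hp]
  contig <- as.character(GenomicRanges::seqnames(hpg))
  genome <- as.character(gset[[contig[1L]]])
  L <- nchar(genome)
  hid <- if (!is.null(hpg$ID)) hpg$ID else hpg$Name
  fam <- if (!is.null(hpg$family)) hpg$family else sub("-[0-9]+$", "", hid)
  st <- BiocGenerics::start(hpg); en <- BiocGenerics::end(hpg)
  ext_start <- pmax(1L, st - flank)
  ext_end <- pmin(L, en + flank)
  hairpins <- data.frame(
    hairpin_id = hid, family = fam, contig = contig, start = st, end = en,
    strand = as.character(BiocGenerics::strand(hpg)),
    hp_len = en - st + 1L, stem_len = NA_integer_,
    sequence = substring(genome, st, en),
    ext_start = ext_start, ext_end = ext_end,
    extended_sequence = substring(genome, ext_start, ext_end),
    stringsAsFactors = FALSE)

  mg <- ann[is_mat]
  parent <- if (!is.null(mg$Derives_from)) as.character(mg$Derives_from)
            else NA_character_
  if (anyNA(parent)) {
    ov <- GenomicRanges::findOverlaps(mg, hpg, select = "first")
    parent[is.na(parent)] <- hid[ov[is.na(parent)]]
  }
  off <- hairpins$ext_start[match(parent, hairpins$hairpin_id)] - 1L
  mname <- if (!is.null(mg$Name)) mg$Name else mg$ID
  arm <- ifelse(grepl("-5p$", mname), "5p",
                ifelse(grepl("-3p$", mname), "3p", NA))
  mstart <- BiocGenerics::start(mg) - off
  mend <- BiocGenerics::end(mg) - off
  if (anyNA(arm)) {
    # fall back to the position relative to the hairpin midpoint
    mid <- (hairpins$start + hairpins$end)[match(parent,
                                                 hairpins$hairpin_id)] / 2 -
      off
    arm[is.na(arm)] <- ifelse((mstart + mend)[is.na(arm)] / 2 < mid[is.na(arm)],
                              "5p", "3p")
  }
  matures <- data.frame(
    hairpin_id = parent,
    family = hairpins$family[match(parent, hairpins$hairpin_id)],
    name = mname, arm = arm, start = mstart, end = mend,
    stringsAsFactors = FALSE)
  structure(list(genome = genome, contig = contig[1L], hairpins = hairpins,
                 matures = matures, sisters_truth = data.frame(),
                 decoy = NULL, flank = flank, params = list()),
            class = "srna_reference")
}

#' Read a sample-to-group table
#' @param path TSV with columns sample_id and group.
#' @return named character vector sample_id -> group.
#' @export
read_groups <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "group") %in% names(tb)))
  stats::setNames(tb$group, tb$sample_id)
}

#' Write catalog, counts and isomiR detail
#'
#' Writes the species catalog as GFF3 in extended-hairpin coordinates, a
#' FASTA of representative sequences, the species x samples count matrix as
#' TSV, and the isomiR detail table as TSV.
#'
#' @param catalog a `species_catalog`.
#' @param agg result of [aggregate_counts()].
#' @param dir output directory.
#' @return invisibly, the named vector of written paths.
#' @export
write_catalog <- function(catalog, agg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- catalog$species
  paths <- c()
  if (nrow(sp)) {
    gr <- GenomicRanges::GRanges(
      seqnames = sp$hairpin_id,
      ranges = IRanges::IRanges(sp$start, sp$end), strand = "+",
      type = "ncRNA", ID = sp$species_id, Name = sp$species_id,
      class = sp$class, family = sp$family)
    gpath <- file.path(dir, "catalog.gff3")
    rtracklayer::export(gr, gpath, format = "gff3")
    fpath <- file.path(dir, "representatives.fa")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(
      stats::setNames(sp$representative_sequence, sp$species_id)), fpath)
    paths <- c(catalog = gpath, fasta = fpath)
  }
  cpath <- file.path(dir, "counts.tsv")
  utils::write.table(data.frame(species_id = rownames(agg$counts),
                                agg$counts, check.names = FALSE),
                     cpath, sep = "\t", quote = FALSE, row.names = FALSE)
  ipath <- file.path(dir, "isomir_detail.tsv")
  utils::write.table(agg$isomir_detail, ipath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, counts = cpath, isomir_detail = ipath))
}
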