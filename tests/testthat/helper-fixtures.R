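# programmatic fixtures shared across test files

tiny_ref <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_reference(n_hairpins = 8L, genome_length = 20000L,
                                   seed = 11L, family_copies = 3L)
    cache
  }
})

write_test_fastq <- function(path, reads, quals) {
  stopifnot(length(reads) == length(quals))
  qstr <- vapply(quals, function(q) intToUtf8(q + 33L), character(1))
  writeLines(paste0("@r", seq_along(reads), "\n", reads, "\n+\n", qstr), path)
  path
}

random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

TEST_ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"
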