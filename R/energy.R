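#' @importFrom utils read.delim
NULL

# package-local cache for the parsed energy model
.moRseq_env <- new.env(parent = emptyenv())

# base encoding used by all folding code: A=1, C=2, G=3, U=4
.BASES <- c("A", "C", "G", "U")

#' Encode an RNA/DNA sequence as integer bases
#'
#' Uppercases, treats T as U, and maps A,C,G,U to 1..4. Any other character
#' is an error unless `allow_n = TRUE`, in which case N is encoded as NA.
#'
#' @param seq character scalar.
#' @param allow_n allow ambiguous N bases (encoded NA).
#' @return integer vector of length `nchar(seq)`.
#' @keywords internal
encode_bases <- function(seq, allow_n = FALSE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- chartr("acgtuT", "ACGUUU", seq)
  v <- strsplit(s, "", fixed = TRUE)[[1L]]
  code <- match(v, .BASES)
  if (allow_n) {
    code[v == "N"] <- NA_integer_
    bad <- is.na(code) & v != "N"
  } else {
    bad <- is.na(code)
  }
  if (any(bad)) {
    stop("invalid nucleotide character(s): ",
         paste(unique(v[bad]), collapse = ", "))
  }
  code
}

#' Normalize a nucleotide sequence to RNA uppercase
#' @param seq character vector.
#' @return character vector with T converted to U.
#' @keywords internal
rna_normalize <- function(seq) {
  chartr("acgtuT", "ACGUUU", seq)
}

# 4x4 logical matrices over the A,C,G,U encoding
.pair_matrices <- function() {
  can <- matrix(FALSE, 4, 4, dimnames = list(.BASES, .BASES))
  can["A", "U"] <- can["U", "A"] <- TRUE
  can["C", "G"] <- can["G", "C"] <- TRUE
  can["G", "U"] <- can["U", "G"] <- TRUE
  wob <- matrix(FALSE, 4, 4, dimnames = list(.BASES, .BASES))
  wob["G", "U"] <- wob["U", "G"] <- TRUE
  list(can = can, wobble = wob)
}

#' Load the embedded stacking-energy table
#'
#' Reads the versioned nearest-neighbour stack table shipped with the package
#' (`extdata/stack_energies.tsv`). Motif `XY/ZW` is the stacked 2x2 with the
#' top strand 5'-XY-3' over the bottom strand 3'-ZW-5' (pairs X:Z and Y:W).
#' The rotational symmetry XY/ZW == WZ/YX is applied when expanding the table.
#'
#' @return list with elements `stack` (a 4x4x4x4 numeric array indexed by the
#'   integer codes of X, Y, Z, W; NA where the motif is not two valid pairs),
#'   `init` (helix initiation penalty, kcal/mol), `can` and `wobble`
#'   (4x4 logical pairing matrices).
#' @export
energy_model <- function() {
  if (!is.null(.moRseq_env$model)) return(.moRseq_env$model)
  path <- system.file("extdata", "stack_energies.tsv", package = "moRseq")
  if (path == "") { # not installed yet: developer tree
    path <- file.path("inst", "extdata", "stack_energies.tsv")
  }
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  init <- tab$dG[tab$motif == "INIT"]
  tab <- tab[tab$motif != "INIT", , drop = FALSE]
  pm <- .pair_matrices()
  arr <- array(NA_real_, dim = c(4, 4, 4, 4))
  put <- function(x, y, z, w, val) {
    cur <- arr[x, y, z, w]
    if (is.na(cur)) arr[x, y, z, w] <<- val
  }
  for (r in seq_len(nrow(tab))) {
    m <- tab$motif[r]
    x <- match(substr(m, 1, 1), .BASES); y <- match(substr(m, 2, 2), .BASES)
    z <- match(substr(m, 4, 4), .BASES); w <- match(substr(m, 5, 5), .BASES)
    stopifnot(!anyNA(c(x, y, z, w)), pm$can[x, z], pm$can[y, w])
    put(x, y, z, w, tab$dG[r])
    put(w, z, y, x, tab$dG[r])  # rotational symmetry
  }
  model <- list(stack = arr, init = init, can = pm$can, wobble = pm$wobble)
  .moRseq_env$model <- model
  model
}

#' Stack free energy between two adjacent base pairs
#'
#' @param x,y top-strand bases (5' to 3') as integer codes or single letters.
#' @param z,w bottom-strand bases paired to `x` and `y` respectively.
#' @return stack dG in kcal/mol (NA if either pair is invalid).
#' @export
stack_energy <- function(x, y, z, w) {
  em <- energy_model()
  ix <- function(b) if (is.character(b)) match(rna_normalize(b), .BASES) else b
  em$stack[ix(x), ix(y), ix(z), ix(w)]
}

#' Reverse complement of a DNA/RNA character vector
#' @param seq character vector (ACGT/U).
#' @param rna return RNA alphabet (U) instead of DNA (T).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(seq, rna = FALSE) {
  out <- vapply(seq, function(s) {
    v <- rev(strsplit(chartr("acgtuUT", "ACGTTTT", s), "",
                      fixed = TRUE)[[1L]])
    paste0(chartr("ACGTN", "TGCAN", v), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
  if (rna) out <- chartr("T", "U", out)
  out
}
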