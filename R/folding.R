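#' RNA secondary structure by stacking-energy dynamic programming
#'
#' Finds the minimum free-energy nested structure of a single RNA strand under
#' the package's simplified nearest-neighbour model: every stacked pair (a pair
#' whose inward neighbour is also paired) contributes its stack energy from the
#' embedded table, and every helix is charged one initiation penalty at its
#' innermost pair (this term subsumes hairpin-loop and interior-loop closure).
#' The empty structure has energy zero, so lone pairs — which would cost the
#' initiation penalty without gaining a stack — are never part of an optimum.
#'
#' The recursion is exact for this model: `V(i,j)` is the optimum with (i,j)
#' paired, splitting on whether the inward neighbour (i+1,j-1) is paired
#' (stack) or not (new helix); `U(i,j)` the optimum with (i,j) not paired;
#' `W = min(V, U)`. Ties are broken deterministically by evaluating the
#' stacking branch first (preferring the structure that extends the longest
#' stem), then bifurcations at the smallest split point.
#'
#' @param seq nucleotide string (A/C/G/T/U; T read as U), up to 300 nt.
#' @param min_loop minimum unpaired hairpin-loop length (default 3).
#' @return object of class `fold_result`: list with `seq` (normalized RNA),
#'   `pairs` (two-column matrix of 1-based paired positions, i < j),
#'   `dot_bracket`, and `energy` (kcal/mol, <= 0).
#' @examples
#' fold_hairpin("GGGGGGAAAACCCCCC")
#' @export
fold_hairpin <- function(seq, min_loop = 3L) {
  b <- encode_bases(seq)
  n <- length(b)
  if (n > 300L) stop("sequence longer than 300 nt")
  em <- energy_model()
  if (n < min_loop + 2L) {
    return(.fold_result(seq, matrix(integer(0), 0, 2), 0, n))
  }
  can <- em$can
  INIT <- em$init
  INF <- Inf

  # pairable[i,j]
  P <- matrix(FALSE, n, n)
  for (i in seq_len(n - min_loop - 1L)) {
    j <- (i + min_loop + 1L):n
    P[i, j] <- can[b[i], ][b[j]]
  }
  V <- matrix(INF, n, n)
  U <- matrix(0, n, n)
  W <- matrix(0, n, n)

  stackE <- function(i, j) em$stack[b[i], b[i + 1L], b[j], b[j - 1L]]

  for (d in (min_loop + 1L):(n - 1L)) {
    for (i in seq_len(n - d)) {
      j <- i + d
      # U(i,j): i unpaired, or i paired to some k < j
      u <- W[i + 1L, j]
      ks <- if (i + min_loop + 1L <= j - 1L) (i + min_loop + 1L):(j - 1L) else integer(0)
      if (length(ks)) {
        ks <- ks[P[i, ks]]
        if (length(ks)) {
          wr <- ifelse(ks + 1L > j, 0, W[cbind(ks + 1L, j)])
          u <- min(u, min(V[cbind(i, ks)] + wr))
        }
      }
      U[i, j] <- u
      if (P[i, j]) {
        inner_u <- if (j - i >= 2L) U[i + 1L, j - 1L] else 0
        v <- inner_u + INIT
        if (j - i - 2L >= min_loop + 1L && P[i + 1L, j - 1L]) {
          v2 <- V[i + 1L, j - 1L] + stackE(i, j)
          if (v2 < v) v <- v2
        }
        V[i, j] <- v
        W[i, j] <- min(v, u)
      } else {
        W[i, j] <- u
      }
    }
  }

  # traceback, re-deciding with the same preference order as the recursion
  pairs <- matrix(integer(0), 0, 2)
  eps <- 1e-9
  stack_iv <- list(c(1L, n, 0L))  # (i, j, mode) mode 0 = W, 1 = V
  while (length(stack_iv)) {
    top <- stack_iv[[length(stack_iv)]]
    stack_iv[[length(stack_iv)]] <- NULL
    i <- top[1L]; j <- top[2L]; mode <- top[3L]
    if (j - i < min_loop + 1L) next
    if (mode == 0L) {
      if (P[i, j] && V[i, j] <= U[i, j] + eps) {
        stack_iv[[length(stack_iv) + 1L]] <- c(i, j, 1L)
      } else {
        # U branch
        target <- U[i, j]
        done <- FALSE
        ks <- if (i + min_loop + 1L <= j - 1L) (i + min_loop + 1L):(j - 1L) else integer(0)
        for (k in ks) {
          if (!P[i, k]) next
          wr <- if (k + 1L > j) 0 else W[k + 1L, j]
          if (V[i, k] + wr <= target + eps) {
            stack_iv[[length(stack_iv) + 1L]] <- c(i, k, 1L)
            if (k + 1L <= j) stack_iv[[length(stack_iv) + 1L]] <- c(k + 1L, j, 0L)
            done <- TRUE
            break
          }
        }
        if (!done) stack_iv[[length(stack_iv) + 1L]] <- c(i + 1L, j, 0L)
      }
    } else {
      pairs <- rbind(pairs, c(i, j))
      stacked <- j - i - 2L >= min_loop + 1L && P[i + 1L, j - 1L] &&
        (V[i + 1L, j - 1L] + stackE(i, j) <= V[i, j] + eps)
      if (stacked) {
        stack_iv[[length(stack_iv) + 1L]] <- c(i + 1L, j - 1L, 1L)
      } else if (j - i >= min_loop + 2L) {
        # interior without the (i+1, j-1) pair: expand U(i+1, j-1)
        ii <- i + 1L; jj <- j - 1L
        if (jj - ii >= min_loop + 1L) {
          target <- U[ii, jj]
          done <- FALSE
          ks <- if (ii + min_loop + 1L <= jj - 1L) (ii + min_loop + 1L):(jj - 1L) else integer(0)
          for (k in ks) {
            if (!P[ii, k]) next
            wr <- if (k + 1L > jj) 0 else W[k + 1L, jj]
            if (V[ii, k] + wr <= target + eps) {
              stack_iv[[length(stack_iv) + 1L]] <- c(ii, k, 1L)
              if (k + 1L <= jj) stack_iv[[length(stack_iv) + 1L]] <- c(k + 1L, jj, 0L)
              done <- TRUE
              break
            }
          }
          if (!done) stack_iv[[length(stack_iv) + 1L]] <- c(ii + 1L, jj, 0L)
        }
      }
    }
  }
  energy <- min(W[1L, n], 0)
  .fold_result(seq, pairs, energy, n)
}

.fold_result <- function(seq, pairs, energy, n) {
  db <- rep(".", n)
  if (nrow(pairs)) {
    pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
    db[pairs[, 1L]] <- "("
    db[pairs[, 2L]] <- ")"
  }
  structure(list(seq = rna_normalize(seq), pairs = pairs,
                 dot_bracket = paste0(db, collapse = ""), energy = energy),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$seq, "\n", x$dot_bracket, "\n",
      sprintf("energy: %.2f kcal/mol, %d pairs\n", x$energy, nrow(x$pairs)),
      sep = "")
  invisible(x)
}

#' Score a given nested structure under the embedded energy model
#'
#' Direct evaluation of the model optimized by [fold_hairpin()]: stacked pairs
#' contribute stack energies, and each pair whose inward neighbour is unpaired
#' is charged the helix initiation penalty.
#'
#' @param seq nucleotide string.
#' @param pairs two-column matrix of 1-based paired positions (i < j).
#' @return energy in kcal/mol.
#' @export
structure_energy <- function(seq, pairs) {
  b <- encode_bases(seq)
  em <- energy_model()
  if (!nrow(pairs)) return(0)
  key <- paste(pairs[, 1L], pairs[, 2L])
  inner <- paste(pairs[, 1L] + 1L, pairs[, 2L] - 1L)
  has_inner <- inner %in% key
  e <- 0
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    if (has_inner[r]) {
      e <- e + em$stack[b[i], b[i + 1L], b[j], b[j - 1L]]
    } else {
      e <- e + em$init
    }
  }
  e
}

#' Optimal small RNA:target heteroduplex
#'
#' Computes the minimum-energy antiparallel duplex between a small RNA and a
#' target window: a monotone set of Watson-Crick or G:U pairs scored with the
#' same embedded stack table as [fold_hairpin()], with one initiation penalty
#' per contiguous helix. Positions pairing with N bases are disallowed.
#'
#' @param small_rna nucleotide string (5' to 3').
#' @param target_window nucleotide string (5' to 3').
#' @return object of class `duplex`: list with `pairs` (two-column matrix:
#'   1-based position in the small RNA, 1-based position in the target),
#'   `energy` (kcal/mol, <= 0), `wobble_count`, and `seed_block` (the longest
#'   contiguous fully stacked block, as `c(start, end)` on the small RNA, or
#'   NULL when no pair exists).
#' @export
duplex_fold <- function(small_rna, target_window) {
  a <- encode_bases(small_rna, allow_n = TRUE)
  bfull <- encode_bases(target_window, allow_n = TRUE)
  na <- length(a); nb <- length(bfull)
  em <- energy_model()
  INIT <- em$init
  r <- rev(bfull)  # k indexes the reversed target; pair (i,k): a[i] with r[k]

  canpair <- matrix(FALSE, na, nb)
  for (i in seq_len(na)) {
    if (is.na(a[i])) next
    ok <- !is.na(r) & em$can[a[i], ][ifelse(is.na(r), 1L, r)]
    canpair[i, ] <- ok
  }

  M <- matrix(Inf, na, nb)       # best energy of duplex ending at pair (i,k)
  Pmin <- matrix(Inf, na, nb)    # prefix minimum of M over i' <= i, k' <= k
  for (i in seq_len(na)) {
    k <- seq_len(nb)
    cand <- ifelse(canpair[i, ], INIT, Inf)
    if (i > 1L) {
      prevM <- c(Inf, M[i - 1L, -nb])        # M[i-1, k-1]
      prevP <- c(Inf, Pmin[i - 1L, -nb])     # Pmin[i-1, k-1]
      sv <- rep(Inf, nb)
      kk <- which(k > 1L & canpair[i, ] & c(FALSE, canpair[i - 1L, -nb]))
      if (length(kk)) {
        sv[kk] <- em$stack[cbind(a[i - 1L], a[i], r[kk - 1L], r[kk])]
      }
      cand <- pmin(cand, prevM + sv, prevP + INIT)
      cand[!canpair[i, ]] <- Inf
    }
    M[i, ] <- cand
    upper <- if (i > 1L) Pmin[i - 1L, ] else rep(Inf, nb)
    Pmin[i, ] <- cummin(pmin(upper, cand))
  }

  best <- min(M)
  if (!is.finite(best) || best > 0) {
    return(structure(list(small_rna = rna_normalize(small_rna),
                          target = rna_normalize(target_window),
                          pairs = matrix(integer(0), 0, 2), energy = 0,
                          wobble_count = 0L, seed_block = NULL),
                     class = "duplex"))
  }
  # traceback from the first argmin (smallest i, then k)
  idx <- which(M == best, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE][1L, ]
  i <- idx[1L]; k <- idx[2L]
  eps <- 1e-9
  chain <- matrix(c(i, k), 1L, 2L)
  repeat {
    val <- M[i, k]
    if (abs(val - INIT) < eps) break  # helix start, nothing before
    moved <- FALSE
    if (i > 1L && k > 1L && canpair[i - 1L, k - 1L]) {
      se <- em$stack[a[i - 1L], a[i], r[k - 1L], r[k]]
      if (!is.na(se) && is.finite(M[i - 1L, k - 1L]) &&
          abs(M[i - 1L, k - 1L] + se - val) < eps) {
        i <- i - 1L; k <- k - 1L
        chain <- rbind(c(i, k), chain)
        moved <- TRUE
      }
    }
    if (!moved) {
      # new helix started at (i,k): predecessor is the prefix argmin
      sub <- M[seq_len(i - 1L), seq_len(k - 1L), drop = FALSE]
      tgt <- val - INIT
      hit <- which(abs(sub - tgt) < eps, arr.ind = TRUE)
      if (!nrow(hit)) break
      hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE][1L, ]
      i <- hit[1L]; k <- hit[2L]
      chain <- rbind(c(i, k), chain)
    }
  }
  # convert k (reversed target index) back to target coordinates
  pairs <- cbind(chain[, 1L], nb + 1L - chain[, 2L])
  wob <- sum(em$wobble[cbind(a[pairs[, 1L]], bfull[pairs[, 2L]])])
  # longest contiguous fully stacked run on the small RNA
  seed <- NULL
  if (nrow(chain)) {
    runs <- .contiguous_runs(chain)
    longest <- runs[[which.max(vapply(runs, length, integer(1L)))]]
    seed <- c(chain[longest[1L], 1L], chain[longest[length(longest)], 1L])
  }
  structure(list(small_rna = rna_normalize(small_rna),
                 target = rna_normalize(target_window),
                 pairs = pairs, energy = best,
                 wobble_count = as.integer(wob), seed_block = seed),
            class = "duplex")
}

# split rows of an (i,k) chain into maximal runs of consecutive stacked pairs
.contiguous_runs <- function(chain) {
  n <- nrow(chain)
  if (n == 0L) return(list())
  brk <- c(TRUE, diff(chain[, 1L]) != 1L | diff(chain[, 2L]) != 1L)
  split(seq_len(n), cumsum(brk))
}

#' @export
print.duplex <- function(x, ...) {
  cat(sprintf("duplex: %d pairs (%d G:U), energy %.2f kcal/mol\n",
              nrow(x$pairs), x$wobble_count, x$energy))
  invisible(x)
}
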