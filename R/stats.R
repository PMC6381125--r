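#' @importFrom stats dbinom dnbinom p.adjust pnorm cor sd
NULL

#' Median-of-ratios size factors
#'
#' DESeq-style normalization: each sample's factor is the median, over
#' species with nonzero counts in every sample, of the ratio of the sample's
#' count to the species' geometric mean across samples.
#'
#' @param raw species x samples matrix of raw counts.
#' @return named numeric vector of positive size factors.
#' @export
size_factors <- function(raw) {
  raw <- as.matrix(raw)
  pos <- rowSums(raw > 0) == ncol(raw)
  if (!any(pos))
    stop("no species with nonzero counts in all samples; consider a ",
         "pseudo-reference fallback (not enabled by default)")
  sub <- raw[pos, , drop = FALSE]
  geo <- exp(rowMeans(log(sub)))
  apply(sub, 2L, function(col) median(col / geo))
}

#' Normalize a count matrix by size factors
#' @param raw species x samples matrix.
#' @param sf size factors (computed with [size_factors()] if NULL).
#' @return matrix of normalized counts `raw[, j] / sf[j]`.
#' @export
normalize_counts <- function(raw, sf = NULL) {
  if (is.null(sf)) sf <- size_factors(raw)
  sweep(as.matrix(raw), 2L, sf, "/")
}

#' Method-of-moments common negative-binomial dispersion
#'
#' Pools within-group variability on normalized counts. For normalized
#' counts with per-sample factor s, Var(y) = mu * mean(1/s) + phi * mu^2;
#' the common dispersion is the ratio estimator
#' `sum_i (v_i - m_i * c) / sum_i m_i^2` over species, floored at 0,
#' where v_i is the pooled within-group sample variance and m_i the mean.
#'
#' @param raw species x samples matrix of raw counts.
#' @param groups vector of group labels (>= 2 samples per group).
#' @param sf size factors (computed if NULL).
#' @param min_mean species below this normalized mean are ignored (they
#'   carry almost no dispersion information).
#' @return common dispersion estimate (>= 0).
#' @export
estimate_dispersion <- function(raw, groups, sf = NULL, min_mean = 1) {
  raw <- as.matrix(raw)
  if (all(raw == 0)) stop("all-zero count matrix")
  groups <- as.character(groups)
  stopifnot(ncol(raw) == length(groups), all(table(groups) >= 2L))
  if (is.null(sf)) sf <- size_factors(raw)
  y <- sweep(raw, 2L, sf, "/")
  cc <- mean(1 / sf)
  gl <- unique(groups)
  N <- ncol(y); G <- length(gl)
  ssq <- rep(0, nrow(y))
  for (g in gl) {
    sub <- y[, groups == g, drop = FALSE]
    mu_g <- rowMeans(sub)
    ssq <- ssq + rowSums((sub - mu_g)^2)
  }
  v <- ssq / (N - G)
  m <- rowMeans(y)
  use <- m >= min_mean
  if (!any(use)) stop("no species above min_mean")
  max(0, sum(v[use] - m[use] * cc) / sum(m[use]^2))
}

#' Exact negative-binomial test for one species
#'
#' Two-sided small-sample test of a group-vs-rest contrast: sample counts
#' are first equalized to a common library size (each sample's counts scaled
#' by the geometric-mean size factor over its own, rounded half-to-even),
#' then the test conditions on the total of the two group sums, whose
#' within-group distributions are negative binomial with common dispersion
#' `phi` (a sum of n iid NB(mu, phi) is NB with size n/phi). The two-sided
#' p-value sums the probabilities of all outcomes no more likely than the
#' observed one; at `phi = 0` this reduces exactly to the conditional
#' binomial test.
#'
#' @param counts integer vector of one species' per-sample counts.
#' @param group_mask logical vector, TRUE for the group of interest.
#' @param phi common dispersion (>= 0).
#' @param sf optional size factors for pseudo-count equalization.
#' @return p-value in (0, 1]; 1 when the total count is zero.
#' @export
nb_exact_test <- function(counts, group_mask, phi, sf = NULL) {
  stopifnot(length(counts) == length(group_mask),
            any(group_mask), any(!group_mask))
  if (!is.null(sf)) {
    sf <- sf / exp(mean(log(sf)))
    counts <- round(counts / sf)
  }
  s1 <- sum(counts[group_mask])
  tot <- s1 + sum(counts[!group_mask])
  if (tot == 0) return(1)
  n1 <- sum(group_mask); n2 <- sum(!group_mask)
  s <- 0:tot
  if (phi <= 0) {
    lp <- dbinom(s, tot, n1 / (n1 + n2), log = TRUE)
  } else {
    mu <- tot / (n1 + n2)
    lp <- dnbinom(s, size = n1 / phi, mu = n1 * mu, log = TRUE) +
      dnbinom(tot - s, size = n2 / phi, mu = n2 * mu, log = TRUE)
    mx <- max(lp)
    lp <- lp - (mx + log(sum(exp(lp - mx))))
  }
  pobs <- lp[s1 + 1L]
  min(1, sum(exp(lp[lp <= pobs + 1e-10])))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate control: `q_(i) = min_{k >= i} (n / k) p_(k)`
#' capped at 1, returned in the input order.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  stopifnot(all(p > 0 & p <= 1))
  p.adjust(p, method = "BH")
}

#' Cumulative expression ranking
#'
#' Sorts species by total normalized expression (descending), computes the
#' cumulative expression fraction, and flags species whose total exceeds the
#' third quartile (upper-quartile expression filter) or the median of all
#' species totals.
#'
#' @param normalized species x samples matrix of normalized counts.
#' @return data.frame: species_id, total, rank, cumulative_fraction,
#'   upper_quartile, above_median.
#' @export
cumulative_expression <- function(normalized) {
  normalized <- as.matrix(normalized)
  stopifnot(nrow(normalized) > 0L)
  tot <- rowSums(normalized)
  q3 <- quantile(tot, 0.75, names = FALSE)
  med <- median(tot)
  ord <- order(-tot)
  data.frame(species_id = rownames(normalized)[ord],
             total = tot[ord], rank = seq_along(tot),
             cumulative_fraction = cumsum(tot[ord]) / sum(tot),
             upper_quartile = tot[ord] > q3,
             above_median = tot[ord] > med,
             row.names = NULL, stringsAsFactors = FALSE)
}

# all permutations of 1..n (n small)
.perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Kendall correlation between a moRNA and its cognate miRNA
#'
#' Kendall's tau-b with tie correction, with a one-tailed p-value for
#' positive association: exact permutation enumeration for n <= 8 profiles,
#' normal approximation otherwise.
#'
#' @param morna,mirna numeric expression profiles of equal length.
#' @return list with `tau`, `p` (one-tailed, greater) and `n`; `tau` and `p`
#'   are NA with a `note` when either profile is constant.
#' @export
correlate_pairs <- function(morna, mirna) {
  stopifnot(length(morna) == length(mirna), length(morna) >= 3L)
  n <- length(morna)
  if (sd(morna) == 0 || sd(mirna) == 0) {
    return(list(tau = NA_real_, p = NA_real_, n = n,
                note = "constant profile: tau undefined"))
  }
  tau <- cor(morna, mirna, method = "kendall")
  if (n <= 8L) {
    pm <- .perms(n)
    taus <- apply(pm, 1L, function(ix)
      cor(morna, mirna[ix], method = "kendall"))
    p <- mean(taus >= tau - 1e-12)
  } else {
    z <- 3 * tau * sqrt(n * (n - 1)) / sqrt(2 * (2 * n + 5))
    p <- pnorm(z, lower.tail = FALSE)
  }
  list(tau = tau, p = p, n = n)
}

#' Group-vs-rest differential expression
#'
#' For every group, tests each species with the exact negative-binomial test
#' against all remaining samples, computes the log2 fold change from
#' normalized group means (with a +0.5 pseudocount), adjusts p-values per
#' contrast with Benjamini-Hochberg, and attaches the upper-quartile
#' expression flag used when reporting differentially expressed species.
#'
#' @param raw species x samples matrix of raw counts.
#' @param groups vector of group labels (one per sample).
#' @param sf size factors (computed if NULL).
#' @param phi common dispersion (estimated if NULL).
#' @return data.frame: species_id, contrast, mean_norm, log2fc, pvalue,
#'   qvalue, upper_quartile.
#' @export
de_test <- function(raw, groups, sf = NULL, phi = NULL) {
  raw <- as.matrix(raw)
  groups <- as.character(groups)
  if (is.null(sf)) sf <- size_factors(raw)
  if (is.null(phi)) phi <- estimate_dispersion(raw, groups, sf)
  y <- normalize_counts(raw, sf)
  tot <- rowSums(y)
  uq <- tot > quantile(tot, 0.75, names = FALSE)
  out <- list()
  for (g in unique(groups)) {
    mask <- groups == g
    if (sum(mask) < 2L || sum(!mask) < 2L) next
    pv <- apply(raw, 1L, nb_exact_test, group_mask = mask, phi = phi,
                sf = sf)
    lfc <- log2((rowMeans(y[, mask, drop = FALSE]) + 0.5) /
                  (rowMeans(y[, !mask, drop = FALSE]) + 0.5))
    out[[g]] <- data.frame(species_id = rownames(raw), contrast = g,
                           mean_norm = rowMeans(y), log2fc = lfc,
                           pvalue = pv, qvalue = bh_adjust(pv),
                           upper_quartile = uq, row.names = NULL,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
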