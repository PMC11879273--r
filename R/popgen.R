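#' Collapse an alignment subset into haplotypes
#'
#' Identical sequences are pooled into haplotypes after complete deletion of
#' columns containing N or a gap within the analysed subset (the same
#' missing-data rule used by all diversity statistics here, and DNAsp's
#' default).
#'
#' @param aln a [seal_alignment()].
#' @param subset population labels (character), specimen ids, or integer
#'   indices; \code{NULL} takes every specimen.
#' @return a \code{haplotype_table}: list with \code{haplotypes} (distinct
#'   site patterns on compared sites), \code{counts} (haplotype x population
#'   matrix), \code{assignment} (specimen -> haplotype index),
#'   \code{compared_sites} (alignment columns used) and \code{n}.
#' @export
collapse_haplotypes <- function(aln, subset = NULL) {
  idx <- subset_index(aln, subset)
  m <- aln_matrix(aln, idx)
  keep <- complete_deletion_sites(m)
  key <- if (length(keep)) apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
         else rep("", nrow(m))
  hap <- match(key, unique(key))
  pops <- aln$pops[idx]
  counts <- table(factor(hap, levels = seq_along(unique(key))),
                  factor(pops, levels = unique(pops)))
  counts <- unclass(as.matrix(counts))
  dimnames(counts) <- list(haplotype = paste0("H", seq_len(nrow(counts))),
                           population = unique(pops))
  structure(list(haplotypes = unique(key), counts = counts,
                 assignment = stats::setNames(hap, aln$ids[idx]),
                 compared_sites = keep, n = length(idx)),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("haplotype_table:", length(x$haplotypes), "haplotypes from", x$n,
      "sequences on", length(x$compared_sites), "compared sites\n")
  invisible(x)
}

#' Number of segregating sites
#'
#' Counts compared columns (complete deletion within the subset) at which at
#' least two distinct bases occur.
#'
#' @inheritParams collapse_haplotypes
#' @return integer count S.
#' @export
segregating_sites <- function(aln, subset = NULL) {
  idx <- subset_index(aln, subset)
  if (length(idx) < 2L) stop("need at least 2 sequences")
  m <- aln_matrix(aln, idx)
  keep <- complete_deletion_sites(m)
  if (!length(keep)) return(0L)
  sum(apply(m[, keep, drop = FALSE], 2L, function(col) length(unique(col))) > 1L)
}

#' Haplotype (gene) diversity
#'
#' Hd = n/(n-1) * (1 - sum p_i^2), the small-sample-corrected probability
#' that two randomly drawn sequences carry different haplotypes.
#'
#' @param ht a \code{haplotype_table} from [collapse_haplotypes()].
#' @return Hd in [0, 1].
#' @export
haplotype_diversity <- function(ht) {
  n <- ht$n
  if (n < 2L) stop("need at least 2 sequences")
  p <- rowSums(ht$counts) / n
  (n / (n - 1)) * (1 - sum(p^2))
}

#' Pairwise difference matrix
#'
#' Hamming distances between all sequence pairs of a subset, counted over the
#' compared sites (complete deletion within the subset).
#'
#' @inheritParams collapse_haplotypes
#' @return list with \code{d} (symmetric integer matrix, zero diagonal) and
#'   \code{L_compared} (number of sites the counts refer to).
#' @export
pairwise_differences <- function(aln, subset = NULL) {
  idx <- subset_index(aln, subset)
  if (length(idx) < 2L) stop("need at least 2 sequences")
  m <- aln_matrix(aln, idx)
  keep <- complete_deletion_sites(m)
  m <- m[, keep, drop = FALSE]
  n <- nrow(m)
  # restrict to variable columns: identical columns contribute nothing
  var_cols <- which(apply(m, 2L, function(col) length(unique(col))) > 1L)
  d <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  if (length(var_cols)) {
    mv <- m[, var_cols, drop = FALSE]
    for (i in seq_len(n - 1L)) {
      di <- colSums(t(mv[(i + 1L):n, , drop = FALSE]) != mv[i, ])
      d[i, (i + 1L):n] <- di
      d[(i + 1L):n, i] <- di
    }
  }
  list(d = d, L_compared = length(keep))
}

#' Nucleotide diversity and mean pairwise differences
#'
#' K is the mean number of differences over all C(n,2) sequence pairs; pi is
#' K divided by the number of compared sites. \code{pi_printed} is pi x 100,
#' the scale on which mitogenome studies conventionally print it.
#'
#' @inheritParams collapse_haplotypes
#' @return list with \code{pi}, \code{pi_printed}, \code{K},
#'   \code{L_compared}.
#' @export
nucleotide_diversity <- function(aln, subset = NULL) {
  pd <- pairwise_differences(aln, subset)
  n <- nrow(pd$d)
  K <- mean(pd$d[upper.tri(pd$d)])
  pi <- if (pd$L_compared > 0) K / pd$L_compared else 0
  list(pi = pi, pi_printed = 100 * pi, K = K, L_compared = pd$L_compared)
}

#' Watterson's theta from segregating sites
#'
#' theta_w = S / a_n with a_n = sum_{i=1}^{n-1} 1/i, on the per-locus scale
#' (not per site). Used as the theta entering the Ewens sampling probability.
#'
#' @param S number of segregating sites.
#' @param n number of sequences.
#' @return theta_w.
#' @export
watterson_theta <- function(S, n) {
  if (n < 2L) stop("need at least 2 sequences")
  S / sum(1 / seq_len(n - 1L))
}

#' Ewens sampling probability of the number of haplotypes
#'
#' Probability of observing exactly h distinct haplotypes in a sample of n
#' sequences under the neutral infinite-alleles model with scaled mutation
#' rate theta:
#' P(h | n, theta) = |s(n,h)| theta^h / prod_{i=0}^{n-1} (theta + i),
#' with |s| the unsigned Stirling numbers of the first kind. Computed in log
#' space so it is stable up to the full sample size.
#'
#' @param n sample size (>= 1).
#' @param h observed number of haplotypes (1 <= h <= n).
#' @param theta scaled mutation rate (>= 0).
#' @return probability in [0, 1].
#' @export
ewens_probability <- function(n, h, theta) {
  if (h < 1 || h > n) stop("h must satisfy 1 <= h <= n")
  if (theta < 0) stop("theta must be >= 0")
  if (theta == 0) return(if (h == 1L) 1 else 0)
  exp(log_stirling1_unsigned(n, h) + h * log(theta) -
        sum(log(theta + 0:(n - 1L))))
}

# log |s(n, k)| for k = 1..n by the triangular recurrence
# |s(n,k)| = |s(n-1,k-1)| + (n-1)|s(n-1,k)|, carried in log space.
log_stirling1_unsigned <- function(n, k) {
  prev <- 0  # row n = 1: |s(1,1)| = 1
  if (n == 1L) return(if (k == 1L) 0 else -Inf)
  for (m in 2:n) {
    cur <- numeric(m)
    # k = 1: |s(m,1)| = (m-1)!
    cur[1] <- lgamma(m)
    if (m > 2L) for (j in 2:(m - 1L)) {
      a <- prev[j - 1L]
      b <- log(m - 1) + prev[j]
      hi <- max(a, b)
      cur[j] <- hi + log1p(exp(min(a, b) - hi))
    }
    cur[m] <- 0  # |s(m,m)| = 1
    prev <- cur
  }
  prev[k]
}

#' Diversity summary for one sample set
#'
#' The per-area summary row: sample size, haplotype count, Ewens probability
#' of that count, haplotype diversity, nucleotide diversity, segregating
#' sites and mean pairwise differences — all under complete deletion within
#' the subset.
#'
#' @inheritParams collapse_haplotypes
#' @param area label for the row.
#' @return one-row data.frame with columns \code{Area, N, h, P, Hd,
#'   pi_printed, S, K, L_compared, theta_w}.
#' @export
diversity_stats <- function(aln, subset = NULL, area = "all") {
  idx <- subset_index(aln, subset)
  n <- length(idx)
  ht <- collapse_haplotypes(aln, idx)
  h <- length(ht$haplotypes)
  S <- segregating_sites(aln, idx)
  nd <- nucleotide_diversity(aln, idx)
  theta <- watterson_theta(S, n)
  data.frame(Area = area, N = n, h = h,
             P = ewens_probability(n, h, theta),
             Hd = haplotype_diversity(ht),
             pi_printed = nd$pi_printed, S = S, K = nd$K,
             L_compared = nd$L_compared, theta_w = theta,
             stringsAsFactors = FALSE)
}

#' Per-area diversity table
#'
#' Computes [diversity_stats()] for each declared area plus a pooled total
#' row, mirroring the layout of a per-locality genetic summary table.
#'
#' @param aln a [seal_alignment()].
#' @param areas character vector of population labels; defaults to all
#'   distinct labels in order of appearance.
#' @param total add a pooled "Total" row.
#' @return data.frame, one row per area.
#' @export
diversity_table <- function(aln, areas = unique(aln$pops), total = TRUE) {
  rows <- lapply(areas, function(a) {
    if (length(subset_index(aln, a)) < 2L)  # singleton areas get an NA row
      return(data.frame(Area = a, N = 1L, h = NA_integer_, P = NA_real_,
                        Hd = NA_real_, pi_printed = NA_real_, S = NA_integer_,
                        K = NA_real_, L_compared = NA_integer_,
                        theta_w = NA_real_, stringsAsFactors = FALSE))
    diversity_stats(aln, a, area = a)
  })
  if (total) rows <- c(rows, list(diversity_stats(aln, NULL, area = "Total")))
  do.call(rbind, rows)
}
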