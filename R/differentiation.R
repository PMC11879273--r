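#' Hudson's Kst permutation test of population differentiation
#'
#' Kst = 1 - Ks/Kt, where Ks is the weighted mean of within-population mean
#' pairwise differences (weights proportional to the number of pairs,
#' n_j(n_j-1)/2, the Hudson-Boos-Kaplan pair-count weighting; sample-size
#' weights n_j/n available via \code{weighting}) and Kt is the mean pairwise
#' difference in the pooled sample. Significance is assessed by permuting
#' population labels with group sizes held fixed; the p-value uses the
#' (1 + exceedances)/(n_perm + 1) convention so it is never exactly zero.
#'
#' @param aln a [seal_alignment()].
#' @param popA,popB the two population labels (or id/index subsets).
#' @param n_perm number of label permutations.
#' @param seed RNG seed (mandatory, logged in the result).
#' @param weighting \code{"pairs"} (default) or \code{"size"}.
#' @return list of class \code{kst_result}: \code{kst}, \code{ks}, \code{kt},
#'   \code{p_perm}, \code{n_perm}, \code{seed}, \code{weighting}.
#' @export
kst_test <- function(aln, popA, popB, n_perm = 1000L, seed,
                     weighting = c("pairs", "size")) {
  weighting <- match.arg(weighting)
  ia <- subset_index(aln, popA)
  ib <- subset_index(aln, popB)
  if (length(ia) < 2L || length(ib) < 2L)
    stop("both populations need at least 2 sequences")
  pool <- c(ia, ib)
  pd <- pairwise_differences(aln, pool)$d
  nA <- length(ia)
  n <- length(pool)
  obs <- kst_stat(pd, seq_len(nA), (nA + 1L):n, weighting)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    ga <- sample.int(n, nA)
    kst_stat(pd, ga, setdiff(seq_len(n), ga), weighting)$kst
  }, numeric(1))
  structure(list(kst = obs$kst, ks = obs$ks, kt = obs$kt,
                 p_perm = (1 + sum(perm >= obs$kst)) / (n_perm + 1),
                 n_perm = n_perm, seed = seed, weighting = weighting),
            class = "kst_result")
}

# Kst from a pooled distance matrix and index split.
kst_stat <- function(d, ga, gb, weighting = "pairs") {
  kt <- mean(d[upper.tri(d)])
  if (kt == 0) return(list(kst = 0, ks = 0, kt = 0))
  kA <- mean(d[ga, ga][upper.tri(diag(length(ga)))])
  kB <- mean(d[gb, gb][upper.tri(diag(length(gb)))])
  w <- switch(weighting,
              pairs = c(choose(length(ga), 2), choose(length(gb), 2)),
              size = c(length(ga), length(gb)))
  w <- w / sum(w)
  ks <- w[1] * kA + w[2] * kB
  list(kst = 1 - ks / kt, ks = ks, kt = kt)
}

#' @export
print.kst_result <- function(x, ...) {
  cat(sprintf("Kst = %.4f (Ks = %.3f, Kt = %.3f), p = %.4g [%d permutations, seed %d]\n",
              x$kst, x$ks, x$kt, x$p_perm, x$n_perm, x$seed))
  invisible(x)
}

#' Nei's net nucleotide divergence dA between two populations
#'
#' Per-site uncorrected (p-) distances under complete deletion over the
#' pooled pair of samples: dXY is the mean distance over all between-
#' population pairs, dX and dY the within-population means, and
#' dA = dXY - (dX + dY)/2.
#'
#' @inheritParams kst_test
#' @return list of class \code{da_result}: \code{da}, \code{dxy}, \code{dx},
#'   \code{dy}, \code{L_compared}.
#' @export
da_distance <- function(aln, popA, popB) {
  ia <- subset_index(aln, popA)
  ib <- subset_index(aln, popB)
  if (length(ia) < 2L || length(ib) < 2L)
    stop("both populations need at least 2 sequences")
  pool <- c(ia, ib)
  pd <- pairwise_differences(aln, pool)
  d <- pd$d / pd$L_compared
  nA <- length(ia)
  ga <- seq_len(nA); gb <- (nA + 1L):length(pool)
  dx <- mean(d[ga, ga][upper.tri(diag(nA))])
  dy <- mean(d[gb, gb][upper.tri(diag(length(ib)))])
  dxy <- mean(d[ga, gb])
  structure(list(da = dxy - (dx + dy) / 2, dxy = dxy, dx = dx, dy = dy,
                 L_compared = pd$L_compared),
            class = "da_result")
}

#' @export
print.da_result <- function(x, ...) {
  cat(sprintf("dA = %.5f (dXY = %.5f, dX = %.5f, dY = %.5f) on %d sites\n",
              x$da, x$dxy, x$dx, x$dy, x$L_compared))
  invisible(x)
}

#' Pairwise differentiation matrices for a set of areas
#'
#' Computes Kst (with permutation p-values) above the diagonal and dA below,
#' mirroring the layout of a pairwise differentiation table.
#'
#' @param aln a [seal_alignment()].
#' @param areas population labels to compare (default: all, in order).
#' @param n_perm,seed passed to [kst_test()]; each pair uses a seed offset
#'   derived deterministically from \code{seed}.
#' @return list with matrices \code{kst}, \code{p}, \code{da} and a
#'   \code{combined} data.frame with Kst above / dA below the diagonal.
#' @export
differentiation_matrix <- function(aln, areas = unique(aln$pops),
                                   n_perm = 1000L, seed = 1L) {
  k <- length(areas)
  kst <- p <- da <- matrix(NA_real_, k, k, dimnames = list(areas, areas))
  off <- 0L
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    off <- off + 1L
    kr <- kst_test(aln, areas[i], areas[j], n_perm = n_perm,
                   seed = (seed + off) %% .Machine$integer.max)
    dr <- da_distance(aln, areas[i], areas[j])
    kst[i, j] <- kst[j, i] <- kr$kst
    p[i, j] <- p[j, i] <- kr$p_perm
    da[i, j] <- da[j, i] <- dr$da
  }
  comb <- matrix("", k, k, dimnames = list(areas, areas))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i < j) comb[i, j] <- sprintf("%.3f", kst[i, j])
    if (i > j) comb[i, j] <- sprintf("%.4f", da[i, j])
  }
  list(kst = kst, p = p, da = da,
       combined = as.data.frame(comb, stringsAsFactors = FALSE))
}

#' Taxonomic assessment of pairwise dA values
#'
#' Flags each population pair against the mitogenome divergence thresholds
#' proposed for cetacean taxonomy: dA > 0.0006 for the population-subspecies
#' boundary and dA > 0.008 for species-level divergence.
#'
#' @param da_matrix symmetric numeric matrix of pairwise dA values (or a
#'   single value).
#' @param subspecies,species thresholds (net substitutions per site).
#' @return data.frame with columns \code{pair_a, pair_b, da, level} where
#'   level is one of \code{"population"}, \code{"subspecies"},
#'   \code{"species-level"}.
#' @export
assess_taxonomic_thresholds <- function(da_matrix, subspecies = 0.0006,
                                        species = 0.008) {
  if (is.null(dim(da_matrix)))
    da_matrix <- matrix(c(NA, da_matrix, da_matrix, NA), 2, 2,
                        dimnames = list(c("A", "B"), c("A", "B")))
  nm <- rownames(da_matrix)
  out <- list()
  for (i in seq_len(nrow(da_matrix) - 1L)) for (j in (i + 1L):ncol(da_matrix)) {
    da <- da_matrix[i, j]
    if (is.na(da)) next
    level <- if (da > species) "species-level"
             else if (da > subspecies) "subspecies" else "population"
    out[[length(out) + 1L]] <- data.frame(pair_a = nm[i], pair_b = nm[j],
                                          da = da, level = level,
                                          stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
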