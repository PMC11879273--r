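# Independent brute-force oracles and tiny fixture builders. These are
# written from the definitions, deliberately not sharing code with the
# package internals they check.

toy_alignment <- function(seqs, pops = rep("p", length(seqs)),
                          ids = paste0("s", seq_along(seqs))) {
  seal_alignment(ids, seqs, pops)
}

# Complete deletion by explicit loops: keep columns where no sequence has
# N or "-".
oracle_kept_columns <- function(seqs) {
  L <- nchar(seqs[1])
  kept <- integer()
  for (j in seq_len(L)) {
    col <- substring(seqs, j, j)
    if (!any(col %in% c("N", "-"))) kept <- c(kept, j)
  }
  kept
}

oracle_site_stats <- function(seqs) {
  kept <- oracle_kept_columns(seqs)
  n <- length(seqs)
  # S: columns with >= 2 distinct bases
  S <- 0L
  for (j in kept) {
    if (length(unique(substring(seqs, j, j))) > 1L) S <- S + 1L
  }
  # pairwise differences, K, pi
  total <- 0; npairs <- 0
  for (i in seq_len(n - 1)) for (k in (i + 1):n) {
    d <- 0L
    for (j in kept)
      if (substring(seqs[i], j, j) != substring(seqs[k], j, j)) d <- d + 1L
    total <- total + d; npairs <- npairs + 1
  }
  K <- total / npairs
  # haplotypes and Hd on kept columns
  pat <- vapply(seqs, function(s)
    paste(substring(s, kept, kept), collapse = ""), character(1))
  counts <- as.vector(table(pat))
  Hd <- (n / (n - 1)) * (1 - sum((counts / n)^2))
  list(S = S, K = K, pi = if (length(kept)) K / length(kept) else 0,
       h = length(counts), Hd = Hd, L_compared = length(kept))
}

# Exact Ewens probabilities for small n via integer polynomial expansion of
# the rising factorial: coefficients of theta^k are |s(n, k)|.
oracle_ewens <- function(n, h, theta) {
  coef <- c(1)  # polynomial "1"
  for (i in 0:(n - 1)) {
    # multiply by (theta + i): new_k = old_{k-1} + i * old_k
    coef <- c(0, coef) + i * c(coef, 0)
  }
  stirling <- coef[h + 1]  # coefficient of theta^h
  stirling * theta^h / prod(theta + 0:(n - 1))
}

# Kst recomputed from scratch for two index sets over raw sequences.
oracle_kst <- function(seqs, ga, gb) {
  kept <- oracle_kept_columns(seqs)
  dist1 <- function(i, k) {
    d <- 0L
    for (j in kept)
      if (substring(seqs[i], j, j) != substring(seqs[k], j, j)) d <- d + 1L
    d
  }
  mean_pairs <- function(ix) {
    tot <- 0; np <- 0
    for (a in seq_along(ix[-length(ix)])) for (b in (a + 1):length(ix)) {
      tot <- tot + dist1(ix[a], ix[b]); np <- np + 1
    }
    tot / np
  }
  kt <- mean_pairs(seq_along(seqs))
  if (kt == 0) return(0)
  wa <- choose(length(ga), 2); wb <- choose(length(gb), 2)
  ks <- (wa * mean_pairs(ga) + wb * mean_pairs(gb)) / (wa + wb)
  1 - ks / kt
}

random_toy_seqs <- function(n, L, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i)
    paste(sample(alphabet, L, replace = TRUE), collapse = ""), character(1))
}

# Random similarity transform of a k x 3 configuration.
random_similarity <- function(config) {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  s <- exp(rnorm(1, 0, 0.3))
  sweep(s * config %*% q, 2, rnorm(3, sd = 20), FUN = "+")
}

small_shape_sim <- function(seed, ...) {
  tpl <- make_symmetric_template(n_pairs = 4L, n_mid = 3L)
  shape_sim_config(template = tpl$template, pairing = tpl$pairing,
                   seed = seed, ...)
}

# Hamming distance matrix by explicit substring comparison.
hamming_oracle <- function(seqs) {
  n <- length(seqs)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d[i, j] <- sum(strsplit(seqs[i], "")[[1]] != strsplit(seqs[j], "")[[1]])
  }
  d
}

# igraph view of an intermediate network list (seqs/observed/edges).
mjn_to_igraph_test <- function(net) {
  ig <- igraph::make_empty_graph(n = length(net$seqs), directed = FALSE)
  if (nrow(net$edges))
    ig <- igraph::add_edges(ig, rbind(net$edges$from, net$edges$to),
                            weight = net$edges$weight)
  ig
}
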