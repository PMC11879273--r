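#' @name mjn
#' @title Median-joining haplotype networks
#'
#' @description
#' The median-joining construction of Bandelt, Forster and Roehl combines
#' minimum-spanning networks (all minimum spanning trees superimposed,
#' relaxed by a parameter epsilon) with inferred intermediate haplotypes:
#' quasi-medians of mutually linked triples are added when they lower the
#' cost of connecting the observed haplotypes, the network is rebuilt, and
#' unused (obsolete) median nodes are pruned at the end. Epsilon = 0
#' reproduces the strict construction used by default in network software.
NULL

# Hamming distances between equal-length strings (rows of a char matrix).
hamming_matrix <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  n <- nrow(m)
  d <- matrix(0L, n, n)
  if (n > 1L) for (i in seq_len(n - 1L)) {
    di <- colSums(t(m[(i + 1L):n, , drop = FALSE]) != m[i, ])
    d[i, (i + 1L):n] <- di
    d[(i + 1L):n, i] <- di
  }
  d
}

# Minimax (maximum edge weight along the best path) distances by the
# min-max closure of the distance matrix; O(n^3).
minimax_closure <- function(d) {
  n <- nrow(d)
  m <- d
  for (k in seq_len(n)) {
    mk <- pmax(matrix(m[, k], n, n), matrix(m[k, ], n, n, byrow = TRUE))
    m <- pmin(m, mk)
  }
  m
}

#' Feasible links of the epsilon-relaxed minimum spanning network
#'
#' A link (u, v) is feasible when u and v are not yet connected by links
#' strictly shorter than d(u, v) - epsilon; equivalently, when
#' d(u, v) <= minimax(u, v) + epsilon. With epsilon = 0 the result is the
#' union of all minimum spanning trees.
#'
#' @param haplotypes character vector of distinct equal-length sequences.
#' @param epsilon non-negative integer relaxation.
#' @return data.frame with columns \code{from}, \code{to} (indices into
#'   \code{haplotypes}, from < to) and \code{weight}.
#' @export
build_msn <- function(haplotypes, epsilon = 0L) {
  stopifnot(epsilon >= 0)
  n <- length(haplotypes)
  if (n == 1L)
    return(data.frame(from = integer(), to = integer(), weight = integer()))
  d <- hamming_matrix(haplotypes)
  mm <- minimax_closure(d)
  keep <- which(upper.tri(d) & d <= mm + epsilon, arr.ind = TRUE)
  data.frame(from = keep[, 1], to = keep[, 2],
             weight = d[keep])[order(keep[, 1], keep[, 2]), , drop = FALSE]
}

# Quasi-medians of three equal-length sequences: position-wise majority;
# positions where all three states differ contribute all three resolutions.
quasi_medians <- function(a, b, c, max_medians = 81L) {
  sa <- strsplit(a, "")[[1]]; sb <- strsplit(b, "")[[1]]; sc <- strsplit(c, "")[[1]]
  base <- sa
  free <- integer()
  for (p in seq_along(sa)) {
    states <- c(sa[p], sb[p], sc[p])
    tab <- table(states)
    if (max(tab) >= 2L) base[p] <- names(tab)[which.max(tab)]
    else free <- c(free, p)
  }
  if (!length(free)) return(paste(base, collapse = ""))
  if (3^length(free) > max_medians) return(character())  # degenerate triple
  grid <- expand.grid(lapply(free, function(p) c(sa[p], sb[p], sc[p])),
                      stringsAsFactors = FALSE)
  vapply(seq_len(nrow(grid)), function(r) {
    x <- base; x[free] <- unlist(grid[r, ]); paste(x, collapse = "")
  }, character(1))
}

#' Insert median (inferred) haplotypes into a feasible-link network
#'
#' One pass computes quasi-medians for every mutually linked triple of the
#' current feasible graph, scores each new median by its connection cost
#' d(u,x) + d(v,x) + d(w,x) for its generating triple, and adds all medians
#' within epsilon of the minimal cost of the pass. The feasible network is
#' rebuilt and passes repeat until no node is added.
#'
#' @param haplotypes character vector of distinct observed sequences.
#' @param epsilon relaxation parameter, also used for the cost window.
#' @param max_iter hard cap on insertion passes.
#' @return list with \code{seqs} (observed then medians, medians sorted per
#'   pass), \code{observed} logical vector, \code{edges} feasible links of
#'   the final node set.
#' @export
add_median_vectors <- function(haplotypes, epsilon = 0L, max_iter = 50L) {
  seqs <- haplotypes
  observed <- rep(TRUE, length(seqs))
  for (iter in seq_len(max_iter)) {
    edges <- build_msn(seqs, epsilon)
    tri <- linked_triples(edges, length(seqs))
    if (!nrow(tri)) return(list(seqs = seqs, observed = observed, edges = edges))
    cand <- character(); cost <- numeric()
    for (r in seq_len(nrow(tri))) {
      u <- seqs[tri[r, 1]]; v <- seqs[tri[r, 2]]; w <- seqs[tri[r, 3]]
      for (x in quasi_medians(u, v, w)) {
        if (x %in% seqs || x %in% cand) next
        cand <- c(cand, x)
        cost <- c(cost, str_dist(x, u) + str_dist(x, v) + str_dist(x, w))
      }
    }
    if (!length(cand)) return(list(seqs = seqs, observed = observed, edges = edges))
    new <- sort(unique(cand[cost <= min(cost) + epsilon]))
    seqs <- c(seqs, new)
    observed <- c(observed, rep(FALSE, length(new)))
  }
  stop("median insertion did not terminate in ", max_iter,
       " passes; raise max_iter or lower epsilon")
}

str_dist <- function(a, b)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

# Mutually linked triples (triangles) of an edge list.
linked_triples <- function(edges, n) {
  if (!nrow(edges)) return(matrix(integer(), 0, 3))
  adj <- matrix(FALSE, n, n)
  adj[cbind(edges$from, edges$to)] <- TRUE
  adj[cbind(edges$to, edges$from)] <- TRUE
  out <- list()
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] & seq_len(n) > i)
    if (length(nb) < 2L) next
    for (a in seq_along(nb[-length(nb)])) for (b in (a + 1L):length(nb))
      if (adj[nb[a], nb[b]]) out[[length(out) + 1L]] <- c(i, nb[a], nb[b])
  }
  if (!length(out)) return(matrix(integer(), 0, 3))
  do.call(rbind, out)
}

#' Prune obsolete median nodes
#'
#' Repeatedly deletes inferred nodes of degree at most 2 whose removal
#' leaves the rebuilt network connecting all observed haplotypes at
#' unchanged total cost. Observed haplotypes are never deleted.
#'
#' @param net list as returned by [add_median_vectors()].
#' @param epsilon relaxation used when rebuilding the network.
#' @return the pruned network (same structure).
#' @export
prune_obsolete <- function(net, epsilon = 0L) {
  repeat {
    edges <- build_msn(net$seqs, epsilon)
    total <- sum(edges$weight)
    deg <- tabulate(c(edges$from, edges$to), nbins = length(net$seqs))
    cand <- which(!net$observed & deg <= 2L)
    removed <- FALSE
    for (i in cand) {
      keep <- setdiff(seq_along(net$seqs), i)
      e2 <- build_msn(net$seqs[keep], epsilon)
      if (sum(e2$weight) <= total) {
        net$seqs <- net$seqs[keep]
        net$observed <- net$observed[keep]
        removed <- TRUE
        break
      }
    }
    if (!removed) {
      net$edges <- edges
      return(net)
    }
  }
}

#' Build a median-joining network from a haplotype table
#'
#' Runs the full construction — feasible links, iterative median insertion,
#' obsolete-node pruning — on the distinct haplotypes of a
#' [collapse_haplotypes()] table. Node identity uses the variable columns
#' only (constant columns carry no network information); observed nodes keep
#' their per-population counts.
#'
#' @param ht a \code{haplotype_table}.
#' @param epsilon non-negative integer relaxation (0 = strict construction).
#' @param max_iter cap on median-insertion passes.
#' @return object of class \code{mjn_graph}: \code{seqs} (variable-column
#'   patterns), \code{observed}, \code{counts} (node x population, zero rows
#'   for medians), \code{edges} (\code{from,to,weight}), \code{labels}
#'   (H* for observed, M* for medians), \code{epsilon},
#'   \code{variable_columns} (indices into the compared sites).
#' @export
build_mjn <- function(ht, epsilon = 0L, max_iter = 50L) {
  full <- ht$haplotypes
  m <- do.call(rbind, strsplit(full, "", fixed = TRUE))
  var_cols <- if (length(full) > 1L)
    which(apply(m, 2L, function(col) length(unique(col))) > 1L) else integer()
  pat <- if (length(var_cols))
    apply(m[, var_cols, drop = FALSE], 1L, paste, collapse = "")
  else rep("", length(full))
  ord <- order(pat)
  pat <- pat[ord]
  counts <- ht$counts[ord, , drop = FALSE]
  if (length(pat) == 1L || !nzchar(pat[1])) {
    net <- list(seqs = pat[1], observed = TRUE,
                edges = data.frame(from = integer(), to = integer(),
                                   weight = integer()))
  } else {
    net <- add_median_vectors(pat, epsilon = epsilon, max_iter = max_iter)
    net <- prune_obsolete(net, epsilon = epsilon)
  }
  n_obs <- sum(net$observed)
  cts <- matrix(0L, length(net$seqs), ncol(counts),
                dimnames = list(NULL, colnames(counts)))
  cts[net$observed, ] <- counts[match(net$seqs[net$observed], pat), , drop = FALSE]
  labels <- character(length(net$seqs))
  labels[net$observed] <- paste0("H", seq_len(n_obs))
  labels[!net$observed] <- paste0("M", seq_len(sum(!net$observed)))
  structure(list(seqs = net$seqs, observed = net$observed, counts = cts,
                 edges = net$edges, labels = labels, epsilon = epsilon,
                 variable_columns = var_cols),
            class = "mjn_graph")
}

#' @export
print.mjn_graph <- function(x, ...) {
  cat("mjn_graph:", sum(x$observed), "observed +", sum(!x$observed),
      "median nodes,", nrow(x$edges), "edges, total cost",
      sum(x$edges$weight), "(epsilon =", x$epsilon, ")\n")
  invisible(x)
}

#' Convert a median-joining network to an igraph object
#'
#' @param g an \code{mjn_graph}.
#' @return an undirected \code{igraph} graph with vertex attributes
#'   \code{name}, \code{sequence}, \code{observed}, \code{total_count} and
#'   one \code{count_<population>} attribute per population, and edge
#'   attribute \code{weight}.
#' @export
mjn_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n = length(g$seqs), directed = FALSE)
  ig <- igraph::set_vertex_attr(ig, "name", value = g$labels)
  ig <- igraph::set_vertex_attr(ig, "sequence", value = g$seqs)
  ig <- igraph::set_vertex_attr(ig, "observed", value = g$observed)
  ig <- igraph::set_vertex_attr(ig, "total_count", value = rowSums(g$counts))
  for (p in colnames(g$counts))
    ig <- igraph::set_vertex_attr(ig, paste0("count_", p), value = g$counts[, p])
  if (nrow(g$edges))
    ig <- igraph::add_edges(ig, rbind(g$edges$from, g$edges$to),
                            weight = g$edges$weight)
  ig
}

#' Export a median-joining network
#'
#' @param g an \code{mjn_graph}.
#' @param path output file.
#' @param format \code{"graphml"} or \code{"tsv"} (edge list with node
#'   labels and weights).
#' @export
export_network <- function(g, path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(mjn_igraph(g), path, format = "graphml")
  } else {
    df <- data.frame(from = g$labels[g$edges$from], to = g$labels[g$edges$to],
                     weight = g$edges$weight)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a GraphML network export
#'
#' @param path GraphML file written by [export_network()].
#' @return an \code{igraph} graph.
#' @export
read_network <- function(path) igraph::read_graph(path, format = "graphml")
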