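#' Aligned sequence set with population labels
#'
#' Container for a multiple alignment of equal-length sequences, each tagged
#' with the population (sampling area) it came from. All genetic statistics
#' in the package consume this object.
#'
#' @param ids character vector of unique specimen identifiers.
#' @param seqs character vector of aligned sequences (same length, characters
#'   from \code{A,C,G,T,N,-}); lowercase input is normalised to uppercase.
#' @param pops character vector of population labels, parallel to \code{ids}.
#' @return An object of class \code{seal_alignment}: a list with elements
#'   \code{ids}, \code{seqs}, \code{pops} and \code{L} (alignment length).
#' @export
seal_alignment <- function(ids, seqs, pops) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  pops <- as.character(pops)
  if (length(ids) != length(seqs) || length(ids) != length(pops))
    stop("ids, seqs and pops must have equal length")
  if (anyDuplicated(ids))
    stop("duplicated specimen ids: ", paste(ids[duplicated(ids)], collapse = ", "))
  L <- unique(nchar(seqs))
  if (length(L) != 1L)
    stop("ragged alignment: sequence '", ids[which(nchar(seqs) != L[1])[1]],
         "' has length ", nchar(seqs[which(nchar(seqs) != L[1])[1]]),
         " but first record has ", L[1])
  if (L == 0L) stop("alignment length must be > 0")
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad))
    stop("sequence '", ids[which(bad)[1]], "' contains characters outside A,C,G,T,N,-")
  structure(list(ids = ids, seqs = seqs, pops = pops, L = L),
            class = "seal_alignment")
}

#' @export
print.seal_alignment <- function(x, ...) {
  cat("seal_alignment:", length(x$ids), "sequences x", x$L, "bp;",
      length(unique(x$pops)), "populations\n")
  print(table(x$pops))
  invisible(x)
}

#' Read a FASTA alignment together with a population map
#'
#' @param path path to a FASTA file (wrapped or single-line records).
#' @param popmap_path path to a tab-separated table with header
#'   \code{id<TAB>population}; every FASTA record id must appear in it.
#' @return a [seal_alignment()].
#' @export
read_fasta_alignment <- function(path, popmap_path) {
  dna <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(dna))
  seqs <- as.character(dna)
  popmap <- utils::read.table(popmap_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE, comment.char = "")
  if (!all(c("id", "population") %in% names(popmap)))
    stop("population map must have columns 'id' and 'population'")
  miss <- setdiff(ids, popmap$id)
  if (length(miss))
    stop("ids missing from population map: ", paste(utils::head(miss, 5), collapse = ", "))
  pops <- popmap$population[match(ids, popmap$id)]
  seal_alignment(ids, seqs, pops)
}

#' Write an alignment as FASTA plus a population map
#'
#' @param aln a [seal_alignment()].
#' @param fasta_path,popmap_path output file paths.
#' @export
write_fasta_alignment <- function(aln, fasta_path, popmap_path) {
  x <- Biostrings::BStringSet(aln$seqs)
  names(x) <- aln$ids
  Biostrings::writeXStringSet(x, fasta_path)
  utils::write.table(data.frame(id = aln$ids, population = aln$pops),
                     popmap_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(aln)
}

# Character matrix (n x L) for a subset of specimens; rows named by id.
aln_matrix <- function(aln, subset = NULL) {
  idx <- subset_index(aln, subset)
  m <- do.call(rbind, strsplit(aln$seqs[idx], "", fixed = TRUE))
  rownames(m) <- aln$ids[idx]
  m
}

subset_index <- function(aln, subset = NULL) {
  if (is.null(subset)) return(seq_along(aln$ids))
  if (is.character(subset)) {
    idx <- which(aln$pops %in% subset | aln$ids %in% subset)
  } else idx <- subset
  if (!length(idx)) stop("empty subset")
  idx
}

#' Columns retained under complete deletion
#'
#' Complete deletion drops every alignment column that contains an ambiguous
#' base (N) or a gap in any sequence of the analysed subset, so that all
#' statistics are computed on fully resolved sites and the identity
#' pi * L_compared = K holds exactly.
#'
#' @param m character matrix from an alignment subset.
#' @return integer vector of column indices kept (1-based alignment columns).
#' @keywords internal
complete_deletion_sites <- function(m) {
  which(colSums(m == "N" | m == "-") == 0L)
}
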