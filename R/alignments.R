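#' @useDynLib alloscan, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import stats
#' @import utils
NULL

ALN_ALPHABET <- c("A", "C", "G", "T", "-", "N",
                  "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Construct an aligned set of nucleotide sequences
#'
#' Sequences are stored as an id-indexed character matrix over the DNA
#' alphabet plus gap and IUPAC ambiguity codes.  All rows must have the same
#' length and ids must be unique; lowercase input is uppercased.
#'
#' @param ids character vector of unique sequence identifiers.
#' @param seqs character vector of aligned sequences (same length each).
#' @return An object of class `seq_alignment`.
#' @export
seq_alignment <- function(ids, seqs) {
  stopifnot(length(ids) == length(seqs), length(ids) > 0)
  if (anyDuplicated(ids)) stop("sequence ids must be unique")
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: sequences differ in length")
  mat <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
                nrow = length(ids), byrow = TRUE)
  bad <- setdiff(unique(as.vector(mat)), ALN_ALPHABET)
  if (length(bad) > 0)
    stop("illegal alignment characters: ", paste(bad, collapse = ", "))
  rownames(mat) <- ids
  structure(list(ids = as.character(ids), mat = mat), class = "seq_alignment")
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat(sprintf("<%s> %d sequences x %d columns\n",
              class(x)[1], length(x$ids), ncol(x$mat)))
  invisible(x)
}

#' @export
dim.seq_alignment <- function(x) dim(x$mat)

aln_length <- function(x) ncol(x$mat)

aln_strings <- function(x) {
  stats::setNames(apply(x$mat, 1, paste, collapse = ""), x$ids)
}

aln_subset <- function(x, ids = NULL, cols = NULL) {
  mat <- x$mat
  if (!is.null(ids)) {
    missing <- setdiff(ids, x$ids)
    if (length(missing) > 0)
      stop("ids not in alignment: ", paste(missing, collapse = ", "))
    mat <- mat[ids, , drop = FALSE]
  }
  if (!is.null(cols)) mat <- mat[, cols, drop = FALSE]
  seq_alignment(rownames(mat), apply(mat, 1, paste, collapse = ""))
}

#' Read aligned (or unaligned) FASTA
#'
#' @param path FASTA file.
#' @param aligned require all records to be of equal length (the default);
#'   with `aligned = FALSE` a named character vector of sequences is
#'   returned instead of a `seq_alignment`.
#' @return A [seq_alignment()], or a named character vector.
#' @export
read_fasta <- function(path, aligned = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("FASTA contains no records: ", path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (!aligned) return(seqs)
  seq_alignment(names(seqs), unname(seqs))
}

#' Write sequences to FASTA
#'
#' @param x a `seq_alignment` or named character vector.
#' @param path output file.
#' @export
write_fasta <- function(x, path) {
  seqs <- if (inherits(x, "seq_alignment")) aln_strings(x) else x
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs))
    writeLines(c(paste0(">", names(seqs)[i]), seqs[[i]]), con)
  invisible(path)
}

#' Reverse-complement a nucleotide string
#' @param seq character scalar.
#' @export
rev_comp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Interpret an alignment as codons
#'
#' Validates that the length is divisible by three and that no sequence
#' contains an internal stop codon (universal code).  Codons containing a
#' gap or ambiguity code are treated as missing in all downstream
#' likelihood computations.  A terminal column consisting only of stop or
#' missing codons is trimmed with a message.
#'
#' @param x a [seq_alignment()].
#' @return The alignment with class `codon_alignment` and `n_codons` set.
#' @export
as_codon_alignment <- function(x) {
  stopifnot(inherits(x, "seq_alignment"))
  L <- aln_length(x)
  if (L %% 3 != 0) stop("alignment length ", L, " not divisible by 3")
  idx <- codon_index_matrix(x)   # nseq x ncodon, NA = missing, 0 = stop
  nc <- ncol(idx)
  if (nc > 1 && any(idx[, nc] == 0L, na.rm = TRUE) &&
      all(idx[, nc] %in% c(0L, NA))) {
    message("trimming terminal stop-codon column")
    x <- aln_subset(x, cols = seq_len(L - 3))
    idx <- idx[, -nc, drop = FALSE]
    nc <- nc - 1
  }
  stops <- which(idx == 0L, arr.ind = TRUE)
  if (nrow(stops) > 0)
    stop(sprintf("internal stop codon in '%s' at codon %d",
                 x$ids[stops[1, 1]], stops[1, 2]))
  x$n_codons <- nc
  class(x) <- c("codon_alignment", "seq_alignment")
  x
}

# integer codon states: 1..61 sense codons, 0 stop, NA missing/ambiguous
codon_index_matrix <- function(x) {
  mat <- x$mat
  nc <- ncol(mat) / 3
  out <- matrix(NA_integer_, nrow = nrow(mat), ncol = nc)
  for (j in seq_len(nc)) {
    cods <- paste0(mat[, 3 * j - 2], mat[, 3 * j - 1], mat[, 3 * j])
    out[, j] <- codon_lookup()[cods]
  }
  rownames(out) <- x$ids
  out
}

#' Extract third codon positions
#'
#' @param x a codon-aware alignment (length divisible by 3).
#' @return A [seq_alignment()] of every third column (offset 2, 0-based).
#' @export
third_positions <- function(x) {
  stopifnot(inherits(x, "seq_alignment"))
  L <- aln_length(x)
  if (L %% 3 != 0)
    stop("frame unknown: alignment length not divisible by 3; ",
         "supply a codon-aware alignment")
  aln_subset(x, cols = seq(3, L, by = 3))
}

#' Retain codon columns fixed within each named group
#'
#' A codon column is kept iff within every group all non-missing codons are
#' identical; variation *between* groups is allowed.  Used to check that
#' unfixed terminal-branch polymorphism does not drive selection signals.
#'
#' @param x a [as_codon_alignment()] result.
#' @param groups named list of disjoint tip-id sets.
#' @return The filtered codon alignment; kept codon indices (1-based) in
#'   attribute `kept_sites`.
#' @export
fixed_codon_filter <- function(x, groups) {
  stopifnot(inherits(x, "codon_alignment"))
  all_ids <- unlist(groups)
  if (anyDuplicated(all_ids)) stop("groups must be disjoint")
  for (g in names(groups)) {
    if (!any(groups[[g]] %in% x$ids))
      stop("group '", g, "' has no tips in the alignment")
  }
  idx <- codon_index_matrix(x)
  keep <- rep(TRUE, ncol(idx))
  for (g in groups) {
    rows <- idx[intersect(g, x$ids), , drop = FALSE]
    poly <- apply(rows, 2, function(col) {
      col <- col[!is.na(col)]
      length(unique(col)) > 1
    })
    keep <- keep & !poly
  }
  kept <- which(keep)
  cols <- as.vector(rbind(3 * kept - 2, 3 * kept - 1, 3 * kept))
  out <- as_codon_alignment(aln_subset(x, cols = cols))
  attr(out, "kept_sites") <- kept
  out
}
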