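#' Amino-acid alignment container
#'
#' Validates and wraps an aligned set of protein sequences as a character
#' matrix (one row per sequence, one column per site) over the 20 standard
#' residues plus the gap symbol `-`. Gap-like symbols (`.`, `X`, `?`, `*`)
#' are normalised to `-` and treated as missing data downstream.
#'
#' @param x Named character vector of aligned sequences, or a character
#'   matrix with rownames.
#' @return Object of class `amino_alignment`: a character matrix with
#'   unique rownames.
#' @export
amino_alignment <- function(x) {
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(names(x))) stop("sequences must be named")
    nc <- unique(nchar(x))
    if (length(nc) != 1L)
      stop("all aligned sequences must have equal length; got lengths ",
           paste(sort(nc), collapse = ", "))
    m <- matrix(unlist(strsplit(x, ""), use.names = FALSE),
                nrow = length(x), ncol = nc, byrow = TRUE)
    rownames(m) <- names(x)
  } else if (is.matrix(x) && is.character(x)) {
    m <- x
    if (is.null(rownames(m))) stop("alignment matrix must have rownames")
  } else stop("x must be a named character vector or character matrix")
  m[] <- toupper(m)
  m[m %in% GAP_CHARS] <- "-"
  bad <- setdiff(unique(as.vector(m)), c(AA_ALPHA, "-"))
  if (length(bad))
    stop("invalid residue symbol(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(rownames(m)))
    stop("duplicate sequence names: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  structure(m, class = c("amino_alignment", "matrix", "array"))
}

#' @export
print.amino_alignment <- function(x, ...) {
  cat(sprintf("amino_alignment: %d sequences x %d sites\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Read an aligned protein FASTA file
#'
#' @param file Path to a FASTA file of equal-length aligned sequences.
#' @return An [amino_alignment()].
#' @export
read_alignment <- function(file) {
  if (!file.exists(file)) stop("no such file: ", file)
  a <- ape::read.FASTA(file, type = "AA")
  if (!length(a)) stop("no sequences in ", file)
  if (anyDuplicated(names(a)))
    stop("FASTA with duplicate names in ", file, ": ",
         paste(unique(names(a)[duplicated(names(a))]), collapse = ", "))
  seqs <- vapply(as.character(a), paste, character(1), collapse = "")
  amino_alignment(seqs)
}

#' Write sequences to FASTA
#'
#' @param x An `amino_alignment` or a named character vector of sequences.
#' @param file Output path.
#' @export
write_alignment <- function(x, file) {
  if (inherits(x, "amino_alignment")) {
    seqs <- apply(unclass(x), 1, paste, collapse = "")
  } else seqs <- x
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_along(seqs))
    writeLines(c(paste0(">", names(seqs)[i]), unname(seqs[i])), con)
  invisible(file)
}

#' Collapse an alignment row to a sequence string
#' @param x An `amino_alignment`.
#' @return Named character vector of sequences.
#' @export
alignment_sequences <- function(x) {
  apply(unclass(x), 1, paste, collapse = "")
}

#' Read a rooted tree with internal-node labels from Newick
#'
#' @param file Path to a Newick file.
#' @return An `ape` `phylo` object.
#' @export
read_tree <- function(file) {
  if (!file.exists(file)) stop("no such file: ", file)
  tr <- ape::read.tree(file)
  if (is.null(tr)) stop("could not parse Newick in ", file)
  tr
}

#' Resolve a labelled internal node to its ape node number
#' @keywords internal
.node_number <- function(tree, label) {
  ntip <- length(tree$tip.label)
  labs <- tree$node.label
  if (is.null(labs) || !label %in% labs) {
    avail <- if (is.null(labs)) "none" else
      paste(labs[nzchar(labs)], collapse = ", ")
    stop("no internal node labelled '", label, "'; available labels: ", avail)
  }
  ntip + match(label, labs)
}

## Validate alignment/tree correspondence and branch lengths.
.check_aln_tree <- function(aln, tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(!is.finite(tree$edge.length)))
    stop("non-finite branch length in tree")
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  if (!setequal(rownames(aln), tree$tip.label))
    stop("alignment names and tree tip labels differ: only in alignment [",
         paste(setdiff(rownames(aln), tree$tip.label), collapse = ", "),
         "]; only in tree [",
         paste(setdiff(tree$tip.label, rownames(aln)), collapse = ", "), "]")
  invisible(TRUE)
}
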