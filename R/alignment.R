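# Protein alignment container and FASTA I/O.

#' Construct a protein alignment
#'
#' @param x Character matrix (taxa x columns, single characters) or a named
#'   character vector of equal-length gapped sequences.
#' @return Object of class `protein_alignment`: a character matrix with
#'   unique rownames (taxa), entries from the 20 amino-acid one-letter codes
#'   plus `"-"` for gaps.
#' @export
protein_alignment <- function(x) {
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(names(x)) || anyDuplicated(names(x)))
      stop_pe("input_error", "sequences must have unique names")
    lens <- nchar(x)
    if (length(unique(lens)) != 1)
      stop_pe("input_error", "all sequences must have equal length")
    x <- do.call(rbind, lapply(strsplit(toupper(x), ""), identity))
  }
  if (!is.matrix(x) || !is.character(x))
    stop_pe("input_error", "alignment must be a character matrix")
  if (is.null(rownames(x)) || anyDuplicated(rownames(x)))
    stop_pe("input_error", "alignment rows must have unique taxon names")
  x[] <- toupper(x)
  bad <- !(x %in% c(AA_CODES, GAP_CHAR))
  if (any(bad))
    stop_pe("input_error", "illegal symbols in alignment: %s",
            paste(unique(x[bad]), collapse = " "))
  class(x) <- c("protein_alignment", class(x))
  x
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat(sprintf("<protein_alignment: %d taxa x %d columns>\n",
              nrow(x), ncol(x)))
  invisible(x)
}

#' Read an aligned protein FASTA file
#'
#' @param path FASTA file with `-` gaps.
#' @return A [protein_alignment()].
#' @export
read_fasta <- function(path) {
  aa <- ape::read.FASTA(path, type = "AA")
  m <- toupper(do.call(rbind, as.character(aa)))
  rownames(m) <- names(aa)
  protein_alignment(m)
}

#' Write sequences as FASTA
#'
#' @param x A `protein_alignment`, or a named list/vector of sequences
#'   (character vectors or single strings).
#' @param path Output file.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "protein_alignment")) {
    seqs <- setNames(apply(unclass(x), 1, paste, collapse = ""), rownames(x))
  } else {
    seqs <- vapply(x, function(s) paste(s, collapse = ""), character(1))
    names(seqs) <- names(x)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    writeLines(seqs[[nm]], con)
  }
  invisible(path)
}

# Integer encoding: 1..20 in AA_CODES order, NA for gap.
encode_alignment <- function(aln) {
  m <- match(unclass(aln), AA_CODES)
  dim(m) <- dim(aln)
  rownames(m) <- rownames(aln)
  m
}

# Character vector for one sequence (possibly with gaps) -> single string.
seq_string <- function(s) paste(s, collapse = "")
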