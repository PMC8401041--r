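#' Genome record
#'
#' A lightweight container for a (possibly multi-contig) nucleotide assembly.
#' Sequences are stored as uppercase character strings over \{A,C,G,T,N\};
#' contig names are kept so fragment coordinates can be reported per contig.
#'
#' @param id Strain/assembly identifier.
#' @param contigs Named character vector of contig sequences; a single unnamed
#'   sequence is accepted and named \code{"contig_1"}.
#' @param metadata Optional named list carried along (e.g. planted truth).
#' @return An object of class \code{genome_record}.
#' @export
genome_record <- function(id, contigs, metadata = list()) {
  stopifnot(is.character(id), length(id) == 1L, is.character(contigs))
  if (length(contigs) == 0L || all(!nzchar(contigs))) {
    stop("genome '", id, "' is empty")
  }
  contigs <- toupper(contigs)
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad)) stop("genome '", id, "' contains non-ACGTN characters")
  if (is.null(names(contigs))) {
    names(contigs) <- paste0("contig_", seq_along(contigs))
  }
  structure(
    list(id = id, contigs = contigs, metadata = metadata),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat(
    "<genome_record>", x$id, "-", length(x$contigs), "contig(s),",
    sum(nchar(x$contigs)), "bp\n"
  )
  invisible(x)
}

#' Total length of a genome record
#' @param genome A \code{genome_record}.
#' @return Integer total number of bases.
#' @export
genome_length <- function(genome) sum(nchar(genome$contigs))

# Accept genome_record, ancestral_genome, or a bare string; return a single
# concatenated sequence (used by the evolvers, which are single-contig).
.single_sequence <- function(x) {
  if (inherits(x, "genome_record")) {
    return(paste(x$contigs, collapse = ""))
  }
  if (inherits(x, "ancestral_genome")) {
    return(x$sequence)
  }
  if (is.character(x) && length(x) == 1L) {
    return(toupper(x))
  }
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a nucleotide sequence")
}

#' Reverse complement of a nucleotide string
#' @param x A single nucleotide string.
#' @return The reverse complement as a character string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Read a genome from FASTA
#'
#' @param path FASTA file path.
#' @param id Genome id; defaults to the file name without extension.
#' @return A \code{genome_record} with one entry per FASTA record.
#' @export
read_genome_fasta <- function(path, id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA: ", path)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  contigs <- as.character(ss)
  names(contigs) <- sub("\\s.*$", "", names(ss))
  genome_record(id, contigs)
}

#' Write a genome to FASTA (80-column wrapped)
#'
#' @param genome A \code{genome_record}.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(ss, filepath = path, width = 80L)
  invisible(path)
}
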