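#' Marker sequence container
#'
#' @param strain_id Strain the marker belongs to.
#' @param sequence Nucleotide string; trimmed/padded to the marker window by
#'   \code{\link{extract_marker}}.
#' @param source \code{"supplied"} or \code{"extracted"}.
#' @param strand Strand the locus was found on (\code{"+"} or \code{"-"});
#'   the sequence itself is always reported in marker (+) orientation.
#' @return An object of class \code{marker_sequence}.
#' @export
marker_sequence <- function(strain_id, sequence, source = "supplied",
                            strand = "+") {
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) {
    stop("marker sequence for '", strain_id, "' has non-ACGTN characters")
  }
  structure(list(strain_id = strain_id, sequence = sequence,
                 source = source, strand = strand),
            class = "marker_sequence")
}

#' Extract the rpoD-like marker locus from a genome
#'
#' Seed-and-extend local alignment of the reference marker against both
#' strands of the genome; the best hit is reported in marker orientation and
#' trimmed to the window anchored at reference-marker columns 1 to
#' \code{marker_window}. Extraction fails below 70\% identity to the
#' reference marker.
#'
#' @param genome A \code{genome_record}.
#' @param reference_marker Reference marker nucleotide string (>= 650 bp).
#' @param th A \code{\link{thresholds}} object.
#' @return A \code{\link{marker_sequence}} with \code{source = "extracted"}.
#' @export
extract_marker <- function(genome, reference_marker, th = thresholds()) {
  stopifnot(inherits(genome, "genome_record"))
  reference_marker <- toupper(reference_marker)
  if (nchar(reference_marker) < 650) {
    stop("reference marker must be >= 650 bp")
  }
  hit <- best_local_hit(reference_marker, genome)
  if (is.null(hit) || hit$identity < 70) {
    stop("marker absent: no locus with >= 70% identity to the reference ",
         "marker found in genome '", genome$id, "'")
  }
  contig <- genome$contigs[[hit$ref_contig]]
  region <- substr(contig, hit$ref_start + 1L, hit$ref_end)
  if (hit$strand == "-") region <- revcomp(region)
  # Re-align the marker to the oriented region globally to map reference
  # columns 1..marker_window onto extracted bases.
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(reference_marker), Biostrings::DNAString(region),
    type = "global-local", substitutionMatrix = .sub_mat(),
    gapOpening = 4, gapExtension = 1
  )
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  win <- th$marker_window
  got <- character(0)
  consumed <- 0L
  for (i in seq_along(p)) {
    if (p[i] != "-") consumed <- consumed + 1L
    if (consumed > win) break
    if (s[i] != "-" && consumed >= 1L) got <- c(got, s[i])
  }
  if (consumed < win) {
    stop("marker absent: locus in genome '", genome$id,
         "' covers only ", consumed, " of ", win, " reference columns")
  }
  seq <- paste(got, collapse = "")
  if (nchar(seq) > win) seq <- substr(seq, 1L, win)
  if (nchar(seq) < win) {
    seq <- paste0(seq, strrep("N", win - nchar(seq)))
  }
  marker_sequence(genome$id, seq, source = "extracted", strand = hit$strand)
}

#' Global-alignment identity between two marker windows
#'
#' Needleman--Wunsch global alignment (match +1, mismatch -1, affine gaps);
#' identity is matches / alignment columns x 100. The ambiguity code N counts
#' as a mismatch.
#'
#' @param a,b \code{marker_sequence} objects (or bare strings).
#' @return Identity percent.
#' @export
marker_identity <- function(a, b) {
  sa <- if (inherits(a, "marker_sequence")) a$sequence else toupper(a)
  sb <- if (inherits(b, "marker_sequence")) b$sequence else toupper(b)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(sa), Biostrings::DNAString(sb),
    type = "global", substitutionMatrix = .sub_mat(),
    gapOpening = 4, gapExtension = 1
  )
  .alignment_stats(aln, nchar(sa))$identity
}

#' Pairwise marker identity matrix
#'
#' @param markers Named list of \code{marker_sequence}s (names default to the
#'   strain ids).
#' @return A symmetric matrix of identity percents with a 100 diagonal,
#'   of class \code{marker_identity_matrix}.
#' @export
marker_identity_matrix <- function(markers) {
  ids <- vapply(markers, function(m) m$strain_id, character(1L))
  if (anyDuplicated(ids)) stop("duplicate strain ids in marker set")
  n <- length(ids)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        v <- marker_identity(markers[[i]], markers[[j]])
        m[i, j] <- m[j, i] <- v
      }
    }
  }
  class(m) <- c("marker_identity_matrix", class(m))
  m
}

#' Write a marker identity matrix as TSV (2-decimal percents)
#' @param m A \code{marker_identity_matrix}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_marker_identity_tsv <- function(m, path) {
  out <- cbind(id = rownames(m), as.data.frame(round(unclass(m), 2)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' rpoD species screen against a panel of type-strain markers
#'
#' Identification rule: a hit at 100\% identity to a type-strain marker is
#' CONFIRMED; a hit at or above the 98\% species-level cutoff but below 100\%
#' is a CANDIDATE-NEEDS-ANI (the affiliation must be validated by ANIb >
#' 96.5\%); anything below the cutoff is POTENTIAL-NEW. Ties at the best
#' identity list all co-best type strains.
#'
#' @param query A \code{marker_sequence}.
#' @param type_markers Non-empty list of type-strain \code{marker_sequence}s.
#' @param th A \code{\link{thresholds}} object.
#' @return A list: \code{strain_id}, \code{verdict} (one of
#'   \code{"CONFIRMED"}, \code{"CANDIDATE-NEEDS-ANI"},
#'   \code{"POTENTIAL-NEW"}), \code{best_identity}, \code{candidates}
#'   (co-best type strain ids), \code{identities} (named vector).
#' @export
rpod_screen <- function(query, type_markers, th = thresholds()) {
  if (length(type_markers) == 0L) stop("type marker set is empty")
  ids <- vapply(type_markers, function(m) m$strain_id, character(1L))
  idents <- vapply(type_markers, function(m) marker_identity(query, m),
                   numeric(1L))
  names(idents) <- ids
  best <- max(idents)
  co_best <- ids[idents >= best - 1e-9]
  verdict <- if (best >= th$rpod_exact) {
    "CONFIRMED"
  } else if (best >= th$rpod_species) {
    "CANDIDATE-NEEDS-ANI"
  } else {
    "POTENTIAL-NEW"
  }
  list(strain_id = query$strain_id, verdict = verdict, best_identity = best,
       candidates = co_best, identities = idents)
}
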