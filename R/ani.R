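#' Fragment a genome for ANIb
#'
#' Cuts each contig into consecutive non-overlapping windows of
#' \code{fragment_length}. A terminal fragment shorter than the window is
#' retained only if it is at least 100 bp; shorter tails are dropped to avoid
#' noisy identity estimates.
#'
#' @param genome A \code{genome_record}.
#' @param fragment_length Window length in bp (ANIb uses 1020).
#' @return A data.frame with columns \code{parent_id} (contig), \code{index},
#'   \code{start}, \code{end} (0-based half-open), \code{sequence}.
#' @export
fragment_genome <- function(genome, fragment_length = 1020L) {
  stopifnot(inherits(genome, "genome_record"))
  if (genome_length(genome) == 0L) stop("cannot fragment an empty genome")
  fragment_length <- as.integer(fragment_length)
  rows <- list()
  idx <- 0L
  for (ci in seq_along(genome$contigs)) {
    cname <- names(genome$contigs)[ci]
    cseq <- genome$contigs[[ci]]
    n <- nchar(cseq)
    starts <- seq.int(0L, n - 1L, by = fragment_length)
    for (s in starts) {
      e <- min(s + fragment_length, n)
      if (e - s < fragment_length && e - s < 100L) next
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        parent_id = cname, index = idx, start = s, end = e,
        sequence = substr(cseq, s + 1L, e), stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(parent_id = character(0), index = integer(0),
                      start = integer(0), end = integer(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# Exact k-mer position index of a genome: one hash per contig mapping k-mer
# string -> 1-based start positions. Built once per reference and reused for
# every fragment of every query.
#' Build a k-mer seed index for a reference genome
#' @param genome A \code{genome_record}.
#' @param k Seed length.
#' @return An object of class \code{kmer_index}.
#' @export
kmer_index <- function(genome, k = 15L) {
  stopifnot(inherits(genome, "genome_record"))
  k <- as.integer(k)
  per_contig <- lapply(genome$contigs, function(cseq) {
    n <- nchar(cseq) - k + 1L
    if (n < 1L) return(list())
    kmers <- substring(cseq, seq_len(n), seq_len(n) + k - 1L)
    split(seq_len(n), kmers)
  })
  structure(list(id = genome$id, k = k, contigs = genome$contigs,
                 index = per_contig),
            class = "kmer_index")
}

# Alignment scoring used throughout: match +1, mismatch -1, gap open 4,
# gap extend 1 (penalties as non-negative Biostrings costs).
.pkg_cache <- new.env(parent = emptyenv())
.sub_mat <- function() {
  if (is.null(.pkg_cache$sub_mat)) {
    .pkg_cache$sub_mat <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE
    )
  }
  .pkg_cache$sub_mat
}

# Identity/coverage bookkeeping from a pairwise alignment: identity is
# matches / alignment columns * 100 (N never counts as a match), coverage is
# aligned pattern bases / pattern length.
.alignment_stats <- function(aln, pattern_length) {
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  cols <- length(p)
  matches <- sum(p == s & p != "-" & p != "N")
  p_rng <- Biostrings::pattern(aln)
  list(
    identity = 100 * matches / cols,
    columns = cols,
    matches = matches,
    coverage = (Biostrings::end(p_rng) - Biostrings::start(p_rng) + 1L) /
      pattern_length,
    pattern_start = Biostrings::start(p_rng),
    pattern_end = Biostrings::end(p_rng)
  )
}

# Candidate alignment windows on one contig for one oriented fragment:
# shared k-mers are grouped into diagonal bands and the best-populated bands
# define windows for gapped extension.
.seed_windows <- function(fseq, contig_index, k, contig_len, max_bands = 3L) {
  flen <- nchar(fseq)
  nk <- flen - k + 1L
  if (nk < 1L) return(NULL)
  fk <- substring(fseq, seq_len(nk), seq_len(nk) + k - 1L)
  hits <- contig_index[fk]
  lens <- lengths(hits)
  if (sum(lens) == 0L) return(NULL)
  qpos <- rep.int(seq_len(nk), lens)
  rpos <- unlist(hits, use.names = FALSE)
  diags <- rpos - qpos
  band <- round(diags / 50)
  counts <- sort(table(band), decreasing = TRUE)
  top <- utils::head(names(counts), max_bands)
  windows <- lapply(top, function(b) {
    sel <- band == as.integer(b)
    d_lo <- min(diags[sel]); d_hi <- max(diags[sel])
    ws <- max(1L, d_lo + 1L - 100L)
    we <- min(contig_len, d_hi + flen + 100L)
    c(start = ws, end = we, n_seeds = sum(sel))
  })
  windows
}

# All candidate (oriented fragment, reference window) pairs for one fragment
# sequence against an indexed reference: both strands, up to `max_bands`
# diagonal bands per strand and contig.
.candidate_windows <- function(fseq, idx) {
  out <- list()
  for (strand in c("+", "-")) {
    oriented <- if (strand == "+") fseq else revcomp(fseq)
    for (ci in seq_along(idx$index)) {
      contig_len <- nchar(idx$contigs[[ci]])
      wins <- .seed_windows(oriented, idx$index[[ci]], idx$k, contig_len)
      if (is.null(wins)) next
      for (w in wins) {
        out[[length(out) + 1L]] <- list(
          strand = strand, contig = ci,
          wstart = w[["start"]],
          pattern = oriented,
          subject = substr(idx$contigs[[ci]], w[["start"]], w[["end"]])
        )
      }
    }
  }
  out
}

# Element-wise batched local alignment of candidate pairs; returns per-pair
# score/identity/coverage and subject coordinates (1-based, window-local).
.batch_local_align <- function(patterns, subjects) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(patterns), Biostrings::DNAStringSet(subjects),
    type = "local", substitutionMatrix = .sub_mat(),
    gapOpening = 4, gapExtension = 1
  )
  # identity = matches / alignment columns; columns = matches + mismatches +
  # gap columns on either side (string extraction avoided for speed)
  nm <- Biostrings::nmatch(aln)
  nmm <- Biostrings::nmismatch(aln)
  ind <- Biostrings::nindel(aln)
  gap_cols <- Biostrings::insertion(ind)[, "WidthSum"] +
    Biostrings::deletion(ind)[, "WidthSum"]
  identity <- 100 * nm / (nm + nmm + gap_cols)
  p_rng <- Biostrings::pattern(aln)
  s_rng <- Biostrings::subject(aln)
  data.frame(
    score = Biostrings::score(aln),
    identity = identity,
    pat_start = Biostrings::start(p_rng),
    pat_end = Biostrings::end(p_rng),
    sub_start = Biostrings::start(s_rng),
    sub_end = Biostrings::end(s_rng)
  )
}

#' Best local hit of a fragment against a reference genome
#'
#' Seed-and-extend local alignment: exact k-mer seeds locate candidate
#' diagonal bands on both strands, and the best-scoring gapped extension
#' (affine penalties; match +1, mismatch -1, open 4, extend 1) is returned.
#'
#' @param fragment A one-row data.frame from \code{\link{fragment_genome}}, or
#'   a bare sequence string (length >= 100).
#' @param reference A \code{genome_record} or a prebuilt
#'   \code{\link{kmer_index}}.
#' @param k Seed length (ignored if \code{reference} is an index).
#' @return \code{NULL} when no seed is found; otherwise a list with
#'   \code{fragment_index}, \code{identity} (percent), \code{coverage}
#'   (fraction of fragment aligned), \code{ref_contig}, \code{ref_start},
#'   \code{ref_end} (0-based half-open), \code{strand}, \code{score}.
#' @export
best_local_hit <- function(fragment, reference, k = 15L) {
  if (is.data.frame(fragment)) {
    fseq <- fragment$sequence[1L]
    findex <- fragment$index[1L]
  } else {
    fseq <- toupper(as.character(fragment))
    findex <- NA_integer_
  }
  if (nchar(fseq) < 100L) stop("fragment length must be >= 100 bp")
  idx <- if (inherits(reference, "kmer_index")) {
    reference
  } else {
    kmer_index(reference, k = k)
  }
  cands <- .candidate_windows(fseq, idx)
  if (length(cands) == 0L) return(NULL)
  res <- .batch_local_align(
    vapply(cands, `[[`, character(1L), "pattern"),
    vapply(cands, `[[`, character(1L), "subject")
  )
  b <- which.max(res$score)
  cand <- cands[[b]]
  flen <- nchar(fseq)
  list(
    fragment_index = findex,
    identity = res$identity[b],
    coverage = (res$pat_end[b] - res$pat_start[b] + 1L) / flen,
    ref_contig = names(idx$index)[cand$contig],
    ref_start = cand$wstart - 1L + res$sub_start[b] - 1L,
    ref_end = cand$wstart - 1L + res$sub_end[b],
    strand = cand$strand,
    score = res$score[b]
  )
}

#' Directional fragment-based ANIb between two genomes
#'
#' The query is cut into fragments (\code{\link{fragment_genome}}), each
#' fragment is aligned to the reference (\code{\link{best_local_hit}}), and
#' ANI is the mean identity over hits passing the identity and coverage
#' filters. When no fragment passes, the ANI is flagged undefined (not 0),
#' signalling unrelated genomes.
#'
#' @param query,reference \code{genome_record}s (reference may also be a
#'   prebuilt \code{kmer_index}).
#' @param th A \code{\link{thresholds}} object.
#' @return An object of class \code{ani_result}: \code{query_id},
#'   \code{ref_id}, \code{ani}, \code{aligned_fraction},
#'   \code{n_fragments_used}, \code{n_fragments_total}, \code{undefined}.
#' @export
anib_pairwise <- function(query, reference, th = thresholds()) {
  stopifnot(inherits(query, "genome_record"))
  idx <- if (inherits(reference, "kmer_index")) {
    reference
  } else {
    kmer_index(reference)
  }
  frags <- fragment_genome(query, th$fragment_length)
  if (nrow(frags) == 0L) stop("query genome yields no fragments")
  # gather candidate windows for every fragment, extend them in one batched
  # alignment call, then keep each fragment's best-scoring hit
  cands <- list()
  owner <- integer(0)
  for (i in seq_len(nrow(frags))) {
    cw <- .candidate_windows(frags$sequence[i], idx)
    if (length(cw)) {
      cands <- c(cands, cw)
      owner <- c(owner, rep.int(i, length(cw)))
    }
  }
  idents <- numeric(0)
  used <- 0L
  if (length(cands)) {
    res <- .batch_local_align(
      vapply(cands, `[[`, character(1L), "pattern"),
      vapply(cands, `[[`, character(1L), "subject")
    )
    for (i in unique(owner)) {
      rows <- which(owner == i)
      b <- rows[which.max(res$score[rows])]
      flen <- nchar(frags$sequence[i])
      coverage <- (res$pat_end[b] - res$pat_start[b] + 1L) / flen
      if (res$identity[b] >= th$min_hit_identity &&
            coverage >= th$min_hit_coverage) {
        used <- used + 1L
        idents <- c(idents, res$identity[b])
      }
    }
  }
  structure(
    list(
      query_id = query$id,
      ref_id = idx$id,
      ani = if (used > 0L) mean(idents) else NA_real_,
      aligned_fraction = used / nrow(frags),
      n_fragments_used = used,
      n_fragments_total = nrow(frags),
      undefined = used == 0L
    ),
    class = "ani_result"
  )
}

#' @export
print.ani_result <- function(x, ...) {
  cat(sprintf("<ani_result> %s -> %s: ANI %s (%d/%d fragments)\n",
              x$query_id, x$ref_id,
              if (x$undefined) "undefined" else sprintf("%.2f", x$ani),
              x$n_fragments_used, x$n_fragments_total))
  invisible(x)
}

#' All-vs-all ANIb with a symmetric summary
#'
#' ANIb is directional; both directions are computed and the symmetric
#' summary for a pair is the arithmetic mean of the two (classification
#' consumes the symmetric value). The diagonal is 100. A pair with an
#' undefined direction has an NA symmetric value.
#'
#' @param genomes Named list of \code{genome_record}s (>= 2).
#' @param th A \code{\link{thresholds}} object.
#' @return A list: \code{symmetric} (matrix), \code{directional} (data.frame
#'   query_id/ref_id/ani/aligned_fraction), \code{summary_statistic}
#'   (\code{"mean_of_directions"}).
#' @export
ani_matrix <- function(genomes, th = thresholds()) {
  if (length(genomes) < 2L) stop("ani_matrix needs at least 2 genomes")
  ids <- vapply(genomes, function(g) g$id, character(1L))
  names(genomes) <- ids
  indexes <- lapply(genomes, kmer_index)
  sym <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  diag(sym) <- 100
  dir_rows <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i == j) next
      r <- anib_pairwise(genomes[[i]], indexes[[j]], th)
      dir_rows[[length(dir_rows) + 1L]] <- data.frame(
        query_id = r$query_id, ref_id = r$ref_id, ani = r$ani,
        aligned_fraction = r$aligned_fraction, undefined = r$undefined,
        stringsAsFactors = FALSE
      )
    }
  }
  directional <- do.call(rbind, dir_rows)
  for (i in seq_along(ids)[-1L]) {
    for (j in seq_len(i - 1L)) {
      ab <- directional$ani[directional$query_id == ids[i] &
                              directional$ref_id == ids[j]]
      ba <- directional$ani[directional$query_id == ids[j] &
                              directional$ref_id == ids[i]]
      v <- if (anyNA(c(ab, ba))) NA_real_ else mean(c(ab, ba))
      sym[ids[i], ids[j]] <- sym[ids[j], ids[i]] <- v
    }
  }
  list(symmetric = sym, directional = directional,
       summary_statistic = "mean_of_directions")
}

#' Write ANI matrices as TSV
#'
#' Symmetric values to 2 decimals (undefined as NA), plus a separate long
#' table of directional values and aligned fractions.
#'
#' @param ani Result of \code{\link{ani_matrix}}.
#' @param dir Output directory.
#' @return Paths of the files written, invisibly.
#' @export
write_ani_tsv <- function(ani, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sym_path <- file.path(dir, "ani_symmetric.tsv")
  m <- round(ani$symmetric, 2)
  utils::write.table(cbind(id = rownames(m), as.data.frame(m)), sym_path,
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  dir_path <- file.path(dir, "ani_directional.tsv")
  utils::write.table(ani$directional, dir_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(c(sym_path, dir_path))
}

#' dDDH value for a genome pair: supplied or surrogate
#'
#' Supplied evidence (a value, or a below-70 flag as printed in the
#' reassignment table) is passed through with \code{source = "supplied"}.
#' Otherwise a clearly labelled surrogate is derived from the symmetric ANI
#' by a monotone piecewise-linear map calibrated so ANI 95 -> dDDH 60,
#' ANI 96.5 -> 70 (the two species boundaries coincide) and ANI 100 -> 100;
#' below ANI 95 the lower segment's slope is extended and clamped at 0.
#'
#' @param pair Character vector of the two genome/strain ids.
#' @param supplied Optional supplied dDDH percent.
#' @param supplied_below_threshold Set \code{TRUE} when the only supplied
#'   evidence is a "dDDH < 70" flag.
#' @param symmetric_ani Symmetric ANI percent (needed for the surrogate).
#' @param th A \code{\link{thresholds}} object.
#' @return An object of class \code{ddh_estimate}: \code{pair}, \code{value}
#'   (NA when only a flag was supplied), \code{below_threshold},
#'   \code{source} (\code{"supplied"} or \code{"surrogate"}).
#' @export
ddh_for_pair <- function(pair, supplied = NULL,
                         supplied_below_threshold = FALSE,
                         symmetric_ani = NULL, th = thresholds()) {
  if (!is.null(supplied)) {
    if (supplied < 0 || supplied > 100) stop("supplied dDDH must be in [0,100]")
    return(structure(list(pair = pair, value = supplied,
                          below_threshold = supplied < th$ddh_species,
                          source = "supplied"),
                     class = "ddh_estimate"))
  }
  if (isTRUE(supplied_below_threshold)) {
    return(structure(list(pair = pair, value = NA_real_,
                          below_threshold = TRUE, source = "supplied"),
                     class = "ddh_estimate"))
  }
  if (is.null(symmetric_ani) || is.na(symmetric_ani)) {
    stop("pair (", paste(pair, collapse = ", "),
         "): neither a supplied dDDH nor a defined ANI is available")
  }
  v <- .ddh_surrogate(symmetric_ani)
  structure(list(pair = pair, value = v,
                 below_threshold = v < th$ddh_species,
                 source = "surrogate"),
            class = "ddh_estimate")
}

# Piecewise-linear ANI -> dDDH map through (95,60), (96.5,70), (100,100);
# the 95-96.5 slope is extended below 95 and clamped at 0.
.ddh_surrogate <- function(ani) {
  stopifnot(ani >= 0, ani <= 100)
  v <- if (ani >= 96.5) {
    70 + (ani - 96.5) * (30 / 3.5)
  } else {
    60 + (ani - 95) * (10 / 1.5)
  }
  max(0, min(100, v))
}
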