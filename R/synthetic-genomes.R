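#' Simulate an ancestral genome
#'
#' Draws an i.i.d. nucleotide sequence with a target GC content. The minimum
#' length is ten ANIb fragments (10 x 1020 bp) so that downstream
#' fragmentation is meaningful.
#'
#' @param length Genome length in bp (>= 10200).
#' @param gc_fraction Expected GC proportion, strictly between 0 and 1.
#' @param seed Integer seed; identical arguments give identical sequences.
#' @param id Identifier for the ancestor.
#' @return An object of class \code{ancestral_genome} with fields
#'   \code{id}, \code{sequence}, \code{gc_fraction}, \code{seed}.
#' @export
simulate_ancestor <- function(length, gc_fraction, seed, id = "ancestor") {
  if (length < 10200) {
    stop("ancestral genome length must be >= 10200 bp (10 ANIb fragments); ",
         "got ", length)
  }
  if (gc_fraction <= 0 || gc_fraction >= 1) {
    stop("gc_fraction must lie strictly between 0 and 1")
  }
  withr_seed <- .with_seed(seed)
  on.exit(withr_seed())
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  seq <- paste(sample(names(p), length, replace = TRUE, prob = p),
               collapse = "")
  structure(
    list(id = id, sequence = seq, gc_fraction = gc_fraction, seed = seed),
    class = "ancestral_genome"
  )
}

# Set the RNG to a fixed state and return a restorer (keeps generator
# behaviour local to the synthetic-data functions).
.with_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Evolve a genome from an ancestor
#'
#' Site-wise uniform substitution (each site mutates independently with
#' probability \code{subst_rate} to a uniformly chosen different base) and
#' optional short (1--10 bp) Poisson-placed insertions/deletions. The realized
#' substitution count is reported as ground truth; indels do not enter the
#' truth divergence.
#'
#' @param ancestor An \code{ancestral_genome}, \code{genome_record}, or a bare
#'   sequence string.
#' @param subst_rate Per-site substitution probability in [0, 0.3].
#' @param indel_rate Per-site indel event probability in [0, 0.3].
#' @param seed Integer seed.
#' @param id Identifier of the evolved genome.
#' @return A list with \code{genome} (a \code{genome_record}),
#'   \code{n_substitutions}, and \code{divergence} (substitutions / ancestral
#'   length).
#' @export
evolve_genome <- function(ancestor, subst_rate, indel_rate = 0, seed = 1L,
                          id = "evolved") {
  if (subst_rate < 0 || subst_rate > 0.3 || indel_rate < 0 || indel_rate > 0.3) {
    stop("subst_rate and indel_rate must lie in [0, 0.3]")
  }
  seq <- .single_sequence(ancestor)
  restore <- .with_seed(seed)
  on.exit(restore())
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  hit <- which(stats::runif(n) < subst_rate)
  if (length(hit)) {
    alphabet <- c("A", "C", "G", "T")
    # uniformly chosen *different* base
    repl <- vapply(chars[hit], function(b) {
      sample(setdiff(alphabet, b), 1L)
    }, character(1L))
    chars[hit] <- repl
  }
  n_sub <- length(hit)
  if (indel_rate > 0) {
    n_events <- stats::rpois(1L, indel_rate * n)
    if (n_events > 0) {
      pos <- sort(sample.int(length(chars), min(n_events, length(chars))),
                  decreasing = TRUE)
      for (p in pos) {
        len <- sample.int(10L, 1L)
        if (stats::runif(1L) < 0.5) { # deletion
          drop <- p:min(p + len - 1L, length(chars))
          chars <- chars[-drop]
        } else { # insertion
          ins <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
          chars <- append(chars, ins, after = p)
        }
      }
    }
  }
  g <- genome_record(id, paste(chars, collapse = ""))
  list(genome = g, n_substitutions = n_sub, divergence = n_sub / n)
}

#' Plant species clusters with known ANI structure
#'
#' Star-like design: a root ancestor is simulated, one intermediate ancestor
#' per species is evolved from it at \code{between_rate / 2}, and strains are
#' evolved from their species ancestor at \code{within_rate / 2}, so realized
#' pairwise divergence is approximately \code{within_rate} within species and
#' approximately \code{between_rate} between species. The planting step is
#' substitution-only, so the recorded truth divergence matrix is the exact
#' pairwise Hamming distance.
#'
#' @param n_species Number of species.
#' @param strains_per_species Strains per species.
#' @param within_rate Target pairwise divergence within a species; must be
#'   below \code{between_rate}. Defaults straddle the 96.5\% ANI boundary.
#' @param between_rate Target pairwise divergence between species.
#' @param seed Integer seed.
#' @param genome_length Genome length in bp.
#' @param gc_fraction Expected GC proportion.
#' @return An object of class \code{evolved_set}: \code{genomes} (named list of
#'   \code{genome_record}), \code{truth_partition} (named character vector
#'   strain -> species label), \code{truth_divergence} (symmetric matrix of
#'   per-site substitution distances), \code{seed}.
#' @export
plant_species_clusters <- function(n_species, strains_per_species,
                                   within_rate = 0.01, between_rate = 0.08,
                                   seed = 1L, genome_length = 12240,
                                   gc_fraction = 0.60) {
  if (within_rate >= between_rate) {
    stop("within_rate must be strictly below between_rate; rates ",
         within_rate, " >= ", between_rate, " cannot separate clusters")
  }
  root <- simulate_ancestor(genome_length, gc_fraction,
                            seed = .child_seed(seed, "root"), id = "root")
  genomes <- list()
  truth <- character(0)
  for (s in seq_len(n_species)) {
    sp_label <- sprintf("species_%02d", s)
    anc <- evolve_genome(root, subst_rate = between_rate / 2, indel_rate = 0,
                         seed = .child_seed(seed, paste0("sp", s)),
                         id = paste0(sp_label, "_anc"))$genome
    for (k in seq_len(strains_per_species)) {
      sid <- sprintf("%s_strain_%02d", sp_label, k)
      g <- evolve_genome(anc, subst_rate = within_rate / 2, indel_rate = 0,
                         seed = .child_seed(seed, paste0("sp", s, "st", k)),
                         id = sid)$genome
      genomes[[sid]] <- g
      truth[sid] <- sp_label
    }
  }
  ids <- names(genomes)
  div <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  seqs <- lapply(genomes, function(g) {
    strsplit(g$contigs[[1L]], "", fixed = TRUE)[[1L]]
  })
  if (length(ids) > 1L) {
    for (i in seq_along(ids)[-length(ids)]) {
      for (j in (i + 1L):length(ids)) {
        d <- mean(seqs[[i]] != seqs[[j]])
        div[i, j] <- div[j, i] <- d
      }
    }
  }
  structure(
    list(genomes = genomes, truth_partition = truth, truth_divergence = div,
         seed = seed),
    class = "evolved_set"
  )
}

# Fixed 30-bp conserved anchors flanking an embedded marker locus; chosen once
# so extraction is deterministic without a gene caller.
.MARKER_ANCHOR_5P <- "GTGGCCTAGACGTTCCAGGATCCGAACTGA"
.MARKER_ANCHOR_3P <- "TCAGGCATCCTGAAGGTTCGCAGATCCGGT"

#' Embed a marker locus into a genome
#'
#' Replaces a stretch of the genome with the marker flanked by fixed 30-bp
#' conserved anchor sequences (genome length is preserved). The truth location
#' is recorded in the genome metadata.
#'
#' @param genome A \code{genome_record} (single contig).
#' @param marker Marker nucleotide string, length >= 650.
#' @param position 0-based offset of the 5' anchor.
#' @param strand \code{"+"} to embed the cassette forward, \code{"-"} to embed
#'   its reverse complement.
#' @return The modified \code{genome_record}; metadata field
#'   \code{marker_truth} holds \code{position}, \code{length}, \code{strand}.
#' @export
embed_marker <- function(genome, marker, position, strand = "+") {
  stopifnot(inherits(genome, "genome_record"))
  marker <- toupper(marker)
  if (nchar(marker) < 650) stop("marker length must be >= 650 bp")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  cassette <- paste0(.MARKER_ANCHOR_5P, marker, .MARKER_ANCHOR_3P)
  if (strand == "-") cassette <- revcomp(cassette)
  seq <- genome$contigs[[1L]]
  if (position < 0 || position + nchar(cassette) > nchar(seq)) {
    stop("marker cassette (", nchar(cassette), " bp at offset ", position,
         ") overlaps past the end of genome '", genome$id, "' (",
         nchar(seq), " bp)")
  }
  new_seq <- paste0(
    substr(seq, 1L, position),
    cassette,
    substr(seq, position + nchar(cassette) + 1L, nchar(seq))
  )
  out <- genome
  out$contigs[[1L]] <- new_seq
  out$metadata$marker_truth <- list(
    position = position, length = nchar(marker), strand = strand
  )
  out
}

#' Write an evolved set to disk
#'
#' Genomes as 80-column FASTA (one file per strain) and the truth tables as
#' TSV (strain id, planted species label, and the divergence matrix columns).
#'
#' @param set An \code{evolved_set}.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_evolved_set <- function(set, dir) {
  stopifnot(inherits(set, "evolved_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in set$genomes) {
    write_genome_fasta(g, file.path(dir, paste0(g$id, ".fasta")))
  }
  truth <- data.frame(
    strain_id = names(set$truth_partition),
    species_label = unname(set$truth_partition),
    stringsAsFactors = FALSE
  )
  truth <- cbind(truth, as.data.frame(set$truth_divergence))
  utils::write.table(truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
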