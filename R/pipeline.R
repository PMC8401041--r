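#' Run the genome-classification pipeline end to end
#'
#' Orchestrates marker extraction and screening (when a reference marker is
#' given), all-vs-all ANIb, species assignment against an optional type-strain
#' panel, single-linkage clustering of new species, synonym collapse of the
#' type panel, and NJ group delineation from marker identities. All
#' randomness flows through \code{seed}. When \code{out_dir} is given, TSV/
#' JSON reports and a manifest sufficient to reproduce the run are written;
#' no partial reports are left behind on error.
#'
#' @param genomes Named list of query \code{genome_record}s.
#' @param type_genomes Optional named list of type-strain genomes.
#' @param reference_marker Optional reference marker sequence; enables the
#'   marker stages.
#' @param th A \code{\link{thresholds}} object.
#' @param seed Integer seed (bootstrap resampling).
#' @param use_ddh_surrogate Resolve ambiguous-zone ANI with the surrogate
#'   dDDH map instead of returning AMBIGUOUS-UNRESOLVED. Off by default; the
#'   surrogate is always labelled as such in outputs.
#' @param description_years Named vector for synonym representatives.
#' @param out_dir Optional report directory.
#' @return A report bundle (list); see fields in the implementation.
#' @export
run_pipeline <- function(genomes, type_genomes = NULL,
                         reference_marker = NULL, th = thresholds(),
                         seed = 1L, use_ddh_surrogate = FALSE,
                         description_years = species_years(),
                         out_dir = NULL) {
  if (length(genomes) == 0L) stop("no query genomes supplied")
  q_ids <- vapply(genomes, function(g) g$id, character(1L))
  names(genomes) <- q_ids
  t_ids <- character(0)
  if (!is.null(type_genomes)) {
    t_ids <- vapply(type_genomes, function(g) g$id, character(1L))
    names(type_genomes) <- t_ids
  }
  bundle <- list(seed = seed, thresholds = unclass(th))

  # marker stage
  markers <- NULL
  screens <- NULL
  if (!is.null(reference_marker)) {
    markers <- lapply(c(genomes, type_genomes), extract_marker,
                      reference_marker = reference_marker, th = th)
    bundle$marker_identity <- marker_identity_matrix(markers)
    if (length(t_ids)) {
      type_markers <- markers[t_ids]
      screens <- lapply(markers[q_ids], rpod_screen,
                        type_markers = type_markers, th = th)
      bundle$rpod_screens <- screens
    }
  }

  # ANI stage
  all_genomes <- c(genomes, type_genomes)
  ani <- ani_matrix(all_genomes, th)
  bundle$ani <- ani
  sym <- ani$symmetric

  # classification stage
  assignments <- vector("list", length(q_ids))
  for (i in seq_along(q_ids)) {
    qi <- q_ids[i]
    if (length(t_ids)) {
      vals <- sym[qi, t_ids]
      if (all(is.na(vals))) {
        assignments[[i]] <- .assignment_without_types(
          qi, "no type strain with defined ANI"
        )
      } else {
        best_t <- t_ids[which.max(vals)]
        ddh <- NULL
        a_val <- sym[qi, best_t]
        if (use_ddh_surrogate && a_val >= th$ani_ambiguous_low &&
              a_val < th$ani_species) {
          ddh <- ddh_for_pair(c(qi, best_t), symmetric_ani = a_val, th = th)
        }
        assignments[[i]] <- assign_species(qi, best_t, a_val, ddh, th)
      }
    } else {
      assignments[[i]] <- .assignment_without_types(qi, "no type panel")
    }
  }
  new_idx <- vapply(assignments, function(a) a$decision == "NEW-SPECIES",
                    logical(1L))
  clustered <- cluster_new_species(assignments[new_idx], sym, th)
  k <- 0L
  for (i in which(new_idx)) {
    k <- k + 1L
    assignments[[i]] <- clustered[[k]]
  }
  bundle$assignments <- assignments
  bundle$new_species_map <- attr(clustered, "species_map")

  # synonym collapse over the type panel
  if (length(t_ids) >= 2L) {
    bundle$synonym_clusters <- collapse_synonyms(t_ids, sym,
                                                 description_years, th)
  }

  # group delineation from marker identities
  if (!is.null(markers) && length(markers) >= 3L) {
    seqs <- vapply(markers, function(m) m$sequence, character(1L))
    names(seqs) <- vapply(markers, function(m) m$strain_id, character(1L))
    bs <- bootstrap_supports(seqs, n_replicates = 100L,
                             seed = .child_seed(seed, "bootstrap"))
    bundle$tree <- bs$tree
    bundle$partition <- delineate(bs$tree, th, min_stem = 1,
                                  min_stem_subgroup = 0.25)
  }

  if (!is.null(out_dir)) .write_bundle(bundle, out_dir)
  bundle
}

.assignment_without_types <- function(strain_id, why) {
  structure(
    list(strain_id = strain_id, closest_type = NA_character_,
         ani = NA_real_, ddh = NULL, decision = "NEW-SPECIES",
         new_species_number = NA_integer_,
         rule_trace = data.frame(rule = "no_type_panel", value = NA_real_,
                                 threshold = NA_real_, outcome = why,
                                 stringsAsFactors = FALSE)),
    class = "taxon_assignment"
  )
}

# Reports are staged in a temporary directory and moved into place only when
# every writer succeeded, so a failing run leaves no partial reports.
.write_bundle <- function(bundle, out_dir) {
  stage <- tempfile("pseudotax_reports_")
  dir.create(stage, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(stage, recursive = TRUE), add = TRUE)
  write_ani_tsv(bundle$ani, stage)
  if (!is.null(bundle$marker_identity)) {
    write_marker_identity_tsv(bundle$marker_identity,
                              file.path(stage, "marker_identity.tsv"))
  }
  decisions <- lapply(bundle$assignments, function(a) {
    list(strain_id = a$strain_id, closest_type = a$closest_type,
         ani = a$ani, decision = a$decision,
         new_species_number = a$new_species_number,
         ddh_source = if (is.null(a$ddh)) NA_character_ else a$ddh$source,
         rule_trace = a$rule_trace)
  })
  jsonlite::write_json(decisions, file.path(stage, "decision_log.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(bundle$partition)) {
    write_partition_tsv(bundle$partition, file.path(stage, "partition.tsv"))
    ape::write.tree(bundle$tree, file.path(stage, "tree.nwk"))
  }
  manifest <- list(
    package = "pseudotax",
    version = as.character(utils::packageVersion("pseudotax")),
    seed = bundle$seed,
    thresholds = bundle$thresholds,
    ani_summary_statistic = bundle$ani$summary_statistic,
    inputs = rownames(bundle$ani$symmetric),
    r_version = R.version.string
  )
  jsonlite::write_json(manifest, file.path(stage, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (f in list.files(stage, full.names = TRUE)) {
    file.copy(f, file.path(out_dir, basename(f)), overwrite = TRUE)
  }
  ok <- TRUE
  invisible(out_dir)
}
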