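#' Assign a strain to a species with the ANI/dDDH decision tree
#'
#' Decision rules (boundaries inclusive on the left of each interval):
#' ANI >= 96.5 -> ASSIGNED to the closest type; 95 <= ANI < 96.5 is the
#' ambiguity zone, resolved by dDDH (>= 70 -> ASSIGNED-VIA-DDH, < 70 ->
#' NEW-SPECIES, no dDDH evidence -> AMBIGUOUS-UNRESOLVED); ANI < 95 ->
#' NEW-SPECIES. The full rule trace is recorded.
#'
#' @param strain_id Strain being classified.
#' @param closest_type Closest type strain / species name.
#' @param ani Symmetric ANI percent to the closest type (must be defined).
#' @param ddh Optional \code{\link{ddh_for_pair}} result.
#' @param th A \code{\link{thresholds}} object.
#' @return An object of class \code{taxon_assignment}: \code{strain_id},
#'   \code{closest_type}, \code{ani}, \code{ddh}, \code{decision},
#'   \code{new_species_number} (assigned later by clustering),
#'   \code{rule_trace} (data.frame rule/value/threshold/outcome).
#' @export
assign_species <- function(strain_id, closest_type, ani, ddh = NULL,
                           th = thresholds()) {
  if (is.null(ani) || is.na(ani)) {
    stop("undefined ANI for pair (", strain_id, ", ", closest_type, ")")
  }
  trace <- list()
  note <- function(rule, value, threshold, outcome) {
    trace[[length(trace) + 1L]] <<- data.frame(
      rule = rule, value = value, threshold = threshold, outcome = outcome,
      stringsAsFactors = FALSE
    )
  }
  if (ani >= th$ani_species) {
    note("ani_species", ani, th$ani_species, "ASSIGNED")
    decision <- "ASSIGNED"
  } else if (ani >= th$ani_ambiguous_low) {
    note("ani_ambiguous_zone", ani,
         paste0("[", th$ani_ambiguous_low, ",", th$ani_species, ")"),
         "consult dDDH")
    if (is.null(ddh)) {
      note("ddh", NA_real_, th$ddh_species, "AMBIGUOUS-UNRESOLVED")
      decision <- "AMBIGUOUS-UNRESOLVED"
    } else if (isTRUE(ddh$below_threshold)) {
      note("ddh", if (is.na(ddh$value)) "<70 (flag)" else ddh$value,
           th$ddh_species, "NEW-SPECIES")
      decision <- "NEW-SPECIES"
    } else {
      note("ddh", if (is.na(ddh$value)) ">=70 (flag)" else ddh$value,
           th$ddh_species, "ASSIGNED-VIA-DDH")
      decision <- "ASSIGNED-VIA-DDH"
    }
  } else {
    note("ani_below_ambiguous", ani, th$ani_ambiguous_low, "NEW-SPECIES")
    decision <- "NEW-SPECIES"
  }
  structure(
    list(strain_id = strain_id, closest_type = closest_type, ani = ani,
         ddh = ddh, decision = decision, new_species_number = NA_integer_,
         rule_trace = do.call(rbind, trace)),
    class = "taxon_assignment"
  )
}

#' @export
print.taxon_assignment <- function(x, ...) {
  cat(sprintf("<taxon_assignment> %s vs %s: ANI %.2f -> %s\n",
              x$strain_id, x$closest_type, x$ani, x$decision))
  invisible(x)
}

#' Collapse synonymous type strains by single-linkage ANI clustering
#'
#' Species are synonymous when their ANIb reaches the species cutoff
#' (optionally minus a tolerance; the published synonymy table contains two
#' pairs at 96.25 and 96.49 that only join with tolerance 0.25). Clusters are
#' single-linkage; the representative is the member with the earliest
#' description year ("earlier synonym" semantics); singleton species are
#' omitted from the output.
#'
#' @param type_ids Character vector of species/type ids.
#' @param symmetric_ani Symmetric ANI matrix covering all \code{type_ids}.
#' @param description_years Named numeric vector species -> year of
#'   description; a cluster missing all years falls back to a lexicographic
#'   representative with a warning.
#' @param th A \code{\link{thresholds}} object.
#' @param tolerance Synonymy tolerance subtracted from the cutoff (default 0).
#' @return List of \code{synonym_cluster} objects (fields \code{members},
#'   \code{representative}, \code{evidence}).
#' @export
collapse_synonyms <- function(type_ids, symmetric_ani,
                              description_years = numeric(0),
                              th = thresholds(), tolerance = 0) {
  missing_ids <- setdiff(type_ids, rownames(symmetric_ani))
  if (length(missing_ids)) {
    stop("ANI matrix does not cover: ", paste(missing_ids, collapse = ", "))
  }
  cutoff <- th$ani_species - tolerance
  labels <- .single_linkage(type_ids, symmetric_ani, cutoff)
  out <- list()
  for (lab in unique(labels)) {
    members <- type_ids[labels == lab]
    if (length(members) < 2L) next
    pairs <- t(utils::combn(members, 2L))
    ev <- data.frame(id_a = pairs[, 1L], id_b = pairs[, 2L],
                     ani = symmetric_ani[pairs], stringsAsFactors = FALSE)
    ev <- ev[ev$ani >= cutoff, , drop = FALSE]
    yrs <- description_years[members]
    if (all(is.na(yrs)) || length(yrs) == 0L) {
      warning("no description year for cluster {",
              paste(members, collapse = ", "),
              "}; representative chosen lexicographically")
      rep_id <- sort(members)[1L]
    } else {
      best <- min(yrs, na.rm = TRUE)
      cand <- members[!is.na(yrs) & yrs == best]
      rep_id <- sort(cand)[1L]
    }
    out[[length(out) + 1L]] <- structure(
      list(members = members, representative = rep_id, evidence = ev),
      class = "synonym_cluster"
    )
  }
  out
}

#' @export
print.synonym_cluster <- function(x, ...) {
  cat("<synonym_cluster>", paste(x$members, collapse = " + "),
      "-> representative:", x$representative, "\n")
  invisible(x)
}

#' Cluster new-species strains into numbered putative species
#'
#' Single-linkage clustering of strains with NEW-SPECIES decisions at the
#' species ANI cutoff; clusters are numbered #1, #2, ... in order of first
#' appearance in the input, and every strain maps to exactly one number.
#'
#' @param unassigned List of \code{taxon_assignment}s, all with decision
#'   NEW-SPECIES.
#' @param symmetric_ani Symmetric ANI matrix covering the strains (an error
#'   is raised for missing pairs).
#' @param th A \code{\link{thresholds}} object.
#' @return The input assignments with \code{new_species_number} filled, plus
#'   attribute \code{"species_map"} (named integer vector strain -> number).
#' @export
cluster_new_species <- function(unassigned, symmetric_ani, th = thresholds()) {
  if (length(unassigned) == 0L) {
    return(structure(list(), species_map = integer(0)))
  }
  decisions <- vapply(unassigned, function(a) a$decision, character(1L))
  if (!all(decisions == "NEW-SPECIES")) {
    stop("cluster_new_species expects only NEW-SPECIES assignments")
  }
  ids <- vapply(unassigned, function(a) a$strain_id, character(1L))
  missing_ids <- setdiff(ids, rownames(symmetric_ani))
  if (length(missing_ids)) {
    stop("ANI matrix missing strains: ", paste(missing_ids, collapse = ", "))
  }
  labels <- .single_linkage(ids, symmetric_ani, th$ani_species)
  out <- lapply(seq_along(unassigned), function(i) {
    a <- unassigned[[i]]
    a$new_species_number <- unname(labels[ids[i]])
    a
  })
  structure(out, species_map = labels)
}

#' Census of a group/subgroup partition table
#'
#' Counts derived from a parsed group table (see
#' \code{\link{parse_fixture}} with schema \code{"table1"}): non-orphan and
#' orphan group counts, species per group and subgroup, newly described
#' species per group, and the focal-group (P. putida) summary. Known
#' anomalies in the printed table (a species listed under two subgroups) are
#' surfaced as warnings in the report, not corrected.
#'
#' @param fixture A parsed table-1 fixture.
#' @param focal_group Group receiving a detailed subgroup census.
#' @return A list of counts; see fields in the implementation.
#' @export
census <- function(fixture, focal_group = "P. putida G") {
  stopifnot(inherits(fixture, "table1_fixture"))
  rows <- fixture$rows
  groups <- unique(rows$group)
  orphan_groups <- unique(rows$group[rows$section == "orphan"])
  non_orphan_groups <- setdiff(groups, orphan_groups)
  species_per_group <- vapply(groups, function(g) {
    sum(rows$n_species[rows$group == g & !rows$is_group_header])
  }, numeric(1L))
  new_per_group <- vapply(groups, function(g) {
    sum(vapply(rows$new_species[rows$group == g], length, integer(1L)))
  }, numeric(1L))
  sub_rows <- rows[rows$group == focal_group & nzchar(rows$subgroup), ,
                   drop = FALSE]
  warnings <- character(0)
  all_listed <- unlist(rows$species)
  dup <- unique(all_listed[duplicated(all_listed)])
  if (length(dup)) {
    warnings <- c(warnings, paste0(
      "species listed more than once (as printed): ",
      paste(dup, collapse = ", ")
    ))
  }
  list(
    n_groups = length(groups),
    n_non_orphan_groups = length(non_orphan_groups),
    n_orphan_groups = length(orphan_groups),
    n_orphan_species = sum(species_per_group[orphan_groups]),
    species_per_group = species_per_group,
    new_species_per_group = new_per_group,
    focal_group = focal_group,
    focal_subgroups = unique(sub_rows$subgroup),
    n_focal_subgroups = length(unique(sub_rows$subgroup)),
    n_focal_species = sum(sub_rows$n_species),
    n_focal_new_species = sum(vapply(sub_rows$new_species, length,
                                     integer(1L))),
    warnings = warnings
  )
}
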