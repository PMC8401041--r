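#' Paths to the packaged table fixtures
#'
#' TSV transcriptions of the published group table (groups/subgroups with
#' newly described species marked "*"), the synonymous-species table, and the
#' strain-reassignment table. The tables are transcribed as printed,
#' including known anomalies (two synonym pairs below the 96.5 cutoff; one
#' species listed under two subgroups; the "P. jutendi" spelling); anomalies
#' are surfaced by the consumers as warnings, never silently corrected.
#'
#' @param which One of \code{"table1"}, \code{"table2"}, \code{"table3"},
#'   \code{"years"}.
#' @return File path.
#' @export
fixture_path <- function(which = c("table1", "table2", "table3", "years")) {
  which <- match.arg(which)
  fn <- switch(which,
    table1 = "table1_groups.tsv",
    table2 = "table2_synonyms.tsv",
    table3 = "table3_reassignments.tsv",
    years = "species_years.tsv"
  )
  path <- system.file("extdata", fn, package = "pseudotax")
  if (!nzchar(path)) stop("packaged fixture not found: ", fn)
  path
}

#' Load the packaged species description-year table
#'
#' Curated from culture-collection records; used to pick earliest-described
#' representatives and group names.
#'
#' @return Named numeric vector species -> year.
#' @export
species_years <- function() {
  df <- utils::read.delim(fixture_path("years"), stringsAsFactors = FALSE)
  stats::setNames(df$year, df$species)
}

#' Parse a packaged (or user) table fixture
#'
#' @param path TSV path.
#' @param schema One of \code{"table1"}, \code{"table2"}, \code{"table3"}.
#' @return A classed fixture object; validation failures report the
#'   offending row number.
#' @export
parse_fixture <- function(path, schema = c("table1", "table2", "table3")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0L) stop("empty fixture: ", path)
  switch(schema,
         table1 = .parse_table1(df),
         table2 = .parse_table2(df),
         table3 = .parse_table3(df))
}

.req_cols <- function(df, cols, path_hint) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop("fixture header missing column(s): ", paste(miss, collapse = ", "))
  }
}

.parse_table1 <- function(df) {
  .req_cols(df, c("section", "group", "subgroup", "species", "n_species",
                  "rpod_range", "anib_range"))
  rows <- df
  rows$n_species <- as.integer(rows$n_species)
  species <- vector("list", nrow(rows))
  new_species <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    raw <- trimws(strsplit(rows$species[i], ";", fixed = TRUE)[[1L]])
    raw <- raw[nzchar(raw)]
    marked <- startsWith(raw, "*")
    species[[i]] <- sub("^\\*", "", raw)
    new_species[[i]] <- sub("^\\*", "", raw[marked])
  }
  rows$species <- species
  rows$new_species <- new_species
  rows$is_group_header <- lengths(species) == 0L
  # validation: listed species count must equal the printed count; a group
  # header's count must equal the sum over its subgroup rows
  for (i in seq_len(nrow(rows))) {
    if (rows$is_group_header[i]) {
      subs <- which(rows$group == rows$group[i] & !rows$is_group_header)
      if (sum(rows$n_species[subs]) != rows$n_species[i]) {
        stop("table1 row ", i, " (", rows$group[i], "): header count ",
             rows$n_species[i], " != sum of subgroup counts ",
             sum(rows$n_species[subs]))
      }
    } else if (length(rows$species[[i]]) != rows$n_species[i]) {
      stop("table1 row ", i, " (", rows$group[i],
           ifelse(nzchar(rows$subgroup[i]), paste0("/", rows$subgroup[i]), ""),
           "): species count ", rows$n_species[i],
           " != list length ", length(rows$species[[i]]))
    }
  }
  structure(list(rows = rows), class = "table1_fixture")
}

.fill_down <- function(x) {
  for (i in seq_along(x)) {
    if (!nzchar(trimws(x[i])) && i > 1L) x[i] <- x[i - 1L]
  }
  x
}

.parse_table2 <- function(df) {
  .req_cols(df, c("group", "species_a", "species_b", "anib",
                  "earlier_synonym"))
  rows <- df
  rows$group <- .fill_down(rows$group)
  rows$species_a <- .fill_down(rows$species_a)
  rows$earlier_synonym <- .fill_down(rows$earlier_synonym)
  rows$anib <- as.numeric(rows$anib)
  for (i in seq_len(nrow(rows))) {
    if (is.na(rows$anib[i]) || rows$anib[i] < 0 || rows$anib[i] > 100) {
      stop("table2 row ", i, ": ANIb must be in [0,100]")
    }
    if (!rows$earlier_synonym[i] %in%
          c(rows$species_a[i], rows$species_b[i])) {
      stop("table2 row ", i, ": earlier synonym '", rows$earlier_synonym[i],
           "' names neither member of the pair")
    }
  }
  structure(list(rows = rows), class = "table2_fixture")
}

.parse_table3 <- function(df) {
  .req_cols(df, c("subgroup", "strain", "closest_type", "anib",
                  "ddh_below_70", "reidentified"))
  rows <- df
  rows$subgroup <- .fill_down(rows$subgroup)
  rows$closest_type <- .fill_down(rows$closest_type)
  rows$reidentified <- .fill_down(rows$reidentified)
  rows$anib <- as.numeric(rows$anib)
  rows$ddh_below_70 <- toupper(trimws(rows$ddh_below_70)) %in%
    c("TRUE", "T", "1", "YES")
  for (i in seq_len(nrow(rows))) {
    if (is.na(rows$anib[i]) || rows$anib[i] < 0 || rows$anib[i] > 100) {
      stop("table3 row ", i, " (", rows$strain[i],
           "): ANIb must be in [0,100]")
    }
    if (!nzchar(rows$strain[i])) stop("table3 row ", i, ": missing strain id")
  }
  structure(list(rows = rows), class = "table3_fixture")
}

#' A supplied dDDH flag as evidence
#'
#' Wraps the binary evidence printed in the reassignment table (an asterisk
#' meaning dDDH < 70\%, or its absence on an ambiguous-zone row that the
#' table nevertheless assigns) as a supplied \code{ddh_estimate} without a
#' numeric value.
#'
#' @param pair Character vector of the two ids.
#' @param below_threshold \code{TRUE} for the asterisk (dDDH < 70).
#' @return A \code{ddh_estimate} with \code{source = "supplied"}.
#' @export
ddh_flag <- function(pair, below_threshold) {
  structure(list(pair = pair, value = NA_real_,
                 below_threshold = isTRUE(below_threshold),
                 source = "supplied"),
            class = "ddh_estimate")
}

#' Classify every strain of the reassignment table
#'
#' Runs the ANI/dDDH decision tree (\code{\link{assign_species}}) on each row
#' of a parsed table-3 fixture. Ambiguous-zone rows are resolved by the
#' supplied dDDH-below-70 flag (asterisk -> NEW-SPECIES; unflagged ->
#' ASSIGNED-VIA-DDH). New-species strains are then grouped into numbered
#' putative species by their shared re-identified label (single-linkage
#' semantics over the table's evidence), numbered in first-appearance order.
#'
#' @param fixture A parsed \code{table3} fixture.
#' @param th A \code{\link{thresholds}} object.
#' @return A list: \code{assignments} (list of \code{taxon_assignment}),
#'   \code{table} (per-strain data.frame with decisions and numbering),
#'   \code{counts} (named: \code{assigned}, \code{new_strains},
#'   \code{new_species}).
#' @export
classify_reassignments <- function(fixture, th = thresholds()) {
  stopifnot(inherits(fixture, "table3_fixture"))
  rows <- fixture$rows
  assignments <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    ani <- rows$anib[i]
    ddh <- if (ani >= th$ani_ambiguous_low && ani < th$ani_species) {
      ddh_flag(c(rows$strain[i], rows$closest_type[i]),
               below_threshold = rows$ddh_below_70[i])
    } else {
      NULL
    }
    assignments[[i]] <- assign_species(rows$strain[i], rows$closest_type[i],
                                       ani, ddh = ddh, th = th)
  }
  decisions <- vapply(assignments, function(a) a$decision, character(1L))
  is_new <- decisions == "NEW-SPECIES"
  # number the new species by shared re-identified label, in row order
  labels <- rows$reidentified[is_new]
  numbers <- match(labels, unique(labels))
  k <- 0L
  for (i in which(is_new)) {
    k <- k + 1L
    assignments[[i]]$new_species_number <- numbers[k]
  }
  tab <- data.frame(
    subgroup = rows$subgroup, strain = rows$strain,
    closest_type = rows$closest_type, anib = rows$anib,
    ddh_below_70 = rows$ddh_below_70, decision = decisions,
    new_species_number = vapply(assignments, function(a) {
      a$new_species_number
    }, integer(1L)),
    reidentified = rows$reidentified,
    stringsAsFactors = FALSE
  )
  list(
    assignments = assignments,
    table = tab,
    counts = c(
      assigned = sum(decisions %in% c("ASSIGNED", "ASSIGNED-VIA-DDH")),
      new_strains = sum(is_new),
      new_species = length(unique(numbers))
    )
  )
}

#' Collapse the synonymy table into clusters
#'
#' Builds a sparse symmetric ANI matrix from the printed pairs and applies
#' \code{\link{collapse_synonyms}}. With the strict cutoff, printed pairs
#' that fall below it drop out of the clustering and are reported as
#' warnings; with \code{tolerance = 0.25} the printed clusters are
#' reproduced in full.
#'
#' @param fixture A parsed \code{table2} fixture.
#' @param th A \code{\link{thresholds}} object.
#' @param tolerance Synonymy tolerance (default 0 = strict).
#' @param description_years Named vector species -> year (defaults to the
#'   packaged table).
#' @return A list: \code{clusters} (list of \code{synonym_cluster}),
#'   \code{warnings} (character), \code{n_clusters}.
#' @export
synonymy_from_table2 <- function(fixture, th = thresholds(), tolerance = 0,
                                 description_years = species_years()) {
  stopifnot(inherits(fixture, "table2_fixture"))
  rows <- fixture$rows
  ids <- unique(c(rbind(rows$species_a, rows$species_b)))
  pairs <- data.frame(id_a = rows$species_a, id_b = rows$species_b,
                      value = rows$anib, stringsAsFactors = FALSE)
  m <- .pairs_to_matrix(ids, pairs)
  m[is.na(m)] <- 0 # unmeasured pairs cannot link
  clusters <- collapse_synonyms(ids, m, description_years, th = th,
                                tolerance = tolerance)
  cutoff <- th$ani_species - tolerance
  dropped <- rows[rows$anib < cutoff, , drop = FALSE]
  warnings <- if (nrow(dropped)) {
    sprintf("printed synonym pair (%s, %s) at ANIb %.2f is below cutoff %.2f and was not linked",
            dropped$species_a, dropped$species_b, dropped$anib, cutoff)
  } else {
    character(0)
  }
  list(clusters = clusters, warnings = warnings,
       n_clusters = length(clusters))
}
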