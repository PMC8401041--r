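#' Neighbor-joining tree from a distance matrix
#'
#' Distance-based stand-in for full phylogenetic inference: marker identities
#' are converted to distances (100 - identity) upstream and agglomerated by
#' neighbor joining. Taxa are processed in lexicographic order so tie-breaking
#' is deterministic. Additive matrices are reproduced exactly.
#'
#' @param distance_matrix Symmetric numeric matrix with zero diagonal and
#'   at least 3 labelled taxa.
#' @return An \code{ape::phylo} tree (unrooted).
#' @export
nj_tree <- function(distance_matrix) {
  m <- as.matrix(distance_matrix)
  if (is.null(rownames(m))) stop("distance matrix must have taxon labels")
  if (nrow(m) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric")
  }
  if (any(abs(diag(m)) > 1e-12)) stop("distance matrix diagonal must be 0")
  ord <- order(rownames(m))
  ape::nj(m[ord, ord])
}

#' Marker identity matrix to NJ distances
#' @param identity A \code{marker_identity_matrix} (percent identities).
#' @return A distance matrix (100 - identity).
#' @export
identity_to_distance <- function(identity) {
  d <- 100 - unclass(identity)
  diag(d) <- 0
  d
}

# p-distance identity matrix (percent) from an alignment matrix
# (rows = taxa, columns = aligned sites).
.alignment_identity_matrix <- function(aln_mat) {
  n <- nrow(aln_mat)
  ids <- rownames(aln_mat)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      v <- 100 * mean(aln_mat[i, ] == aln_mat[j, ])
      m[i, j] <- m[j, i] <- v
    }
  }
  m
}

#' Bootstrap supports for the NJ tree of a marker alignment
#'
#' Columns are resampled with replacement; each replicate's NJ tree is built
#' from p-distances and the support of an internal edge is the percentage of
#' replicates containing the same bipartition. Supports are attached to the
#' tree as internal node labels. Seed-deterministic and invariant to taxon
#' order.
#'
#' @param alignment Character matrix (rows = taxa with rownames, columns =
#'   aligned sites) or named character vector of equal-length sequences.
#' @param n_replicates Number of bootstrap replicates.
#' @param seed Integer seed.
#' @return A list: \code{tree} (NJ tree of the full alignment with
#'   \code{node.label} supports in percent), \code{supports} (numeric vector
#'   per internal node).
#' @export
bootstrap_supports <- function(alignment, n_replicates = 200L, seed = 1L) {
  aln <- .as_alignment_matrix(alignment)
  restore <- .with_seed(seed)
  on.exit(restore())
  # lexicographic taxon order for order invariance
  aln <- aln[order(rownames(aln)), , drop = FALSE]
  main <- nj_tree(identity_to_distance(.alignment_identity_matrix(aln)))
  reps <- vector("list", n_replicates)
  nc <- ncol(aln)
  for (r in seq_len(n_replicates)) {
    cols <- sample.int(nc, nc, replace = TRUE)
    reps[[r]] <- nj_tree(
      identity_to_distance(.alignment_identity_matrix(aln[, cols,
                                                          drop = FALSE]))
    )
  }
  counts <- ape::prop.clades(main, part = ape::prop.part(reps),
                             rooted = FALSE)
  counts[is.na(counts)] <- 0L
  supports <- 100 * counts / n_replicates
  main$node.label <- as.character(round(supports, 1))
  list(tree = main, supports = supports)
}

.as_alignment_matrix <- function(alignment) {
  if (is.matrix(alignment)) {
    if (is.null(rownames(alignment))) stop("alignment rows must be named")
    return(alignment)
  }
  if (is.character(alignment)) {
    if (is.null(names(alignment))) stop("sequences must be named")
    lens <- nchar(alignment)
    if (length(unique(lens)) != 1L) stop("alignment must be rectangular")
    m <- do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
    rownames(m) <- names(alignment)
    return(m)
  }
  stop("unsupported alignment representation")
}

#' Delineate groups and subgroups on a supported tree
#'
#' Greedy top-down cut of a rooted tree: a clade becomes a group iff its
#' bootstrap support is at least \code{group_support} and its stem branch
#' length is at least \code{min_stem}; leaves absorbed by no qualifying clade
#' become orphan groups. Within each group the same rule with
#' \code{min_stem_subgroup} yields subgroups. The support/branch-length
#' thresholds are explicit operationalizations of a qualitative criterion
#' ("branch length, grouping, and bootstrap values") and are configurable.
#'
#' @param tree A rooted \code{ape::phylo} with \code{node.label} supports, or
#'   an unrooted tree plus \code{outgroup}.
#' @param th A \code{\link{thresholds}} object (uses \code{group_support}).
#' @param min_stem Minimum stem branch length for a group.
#' @param min_stem_subgroup Minimum stem branch length for a subgroup.
#' @param outgroup Optional outgroup taxon id used to root (and then dropped
#'   from the partition). Without it, an unrooted tree is midpoint-rooted and
#'   a note is recorded.
#' @return An object of class \code{group_partition}: data.frame
#'   \code{membership} (taxon, group, subgroup, orphan), list \code{groups},
#'   \code{notes}.
#' @export
delineate <- function(tree, th = thresholds(), min_stem = 1,
                      min_stem_subgroup = 0.25, outgroup = NULL) {
  stopifnot(inherits(tree, "phylo"))
  notes <- character(0)
  if (!is.null(outgroup)) {
    if (!outgroup %in% tree$tip.label) {
      stop("outgroup '", outgroup, "' is not a tree tip")
    }
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE,
                      edgelabel = TRUE)
    tree <- ape::drop.tip(tree, outgroup)
  } else if (!ape::is.rooted(tree)) {
    if (is.null(tree$node.label)) {
      stop("unrooted tree without an outgroup: please supply an outgroup")
    }
    tree <- phangorn::midpoint(tree, node.labels = "label")
    notes <- c(notes, "tree was midpoint-rooted (no outgroup supplied)")
  }
  if (is.null(tree$node.label)) {
    stop("tree has no support values (node labels)")
  }
  supports <- suppressWarnings(as.numeric(tree$node.label))
  n_tip <- length(tree$tip.label)
  root_node <- n_tip + 1L
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  stem_len <- numeric(max(tree$edge))
  stem_len[tree$edge[, 2L]] <- tree$edge.length
  tips_under <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    unlist(lapply(children[[as.character(node)]], tips_under))
  }
  qualifies <- function(node, min_len) {
    if (node <= n_tip) return(FALSE)
    sup <- supports[node - n_tip]
    !is.na(sup) && sup >= th$group_support && stem_len[node] >= min_len
  }
  # Greedy top-down: recurse from the root; the first qualifying clade on a
  # path becomes a unit and is not split further at this level.
  cut_units <- function(node, min_len, at_root) {
    if (!at_root && qualifies(node, min_len)) {
      return(list(list(tips = tips_under(node), clade = TRUE)))
    }
    if (node <= n_tip) {
      return(list(list(tips = tree$tip.label[node], clade = FALSE)))
    }
    unlist(lapply(children[[as.character(node)]], cut_units,
                  min_len = min_len, at_root = FALSE),
           recursive = FALSE)
  }
  units <- cut_units(root_node, min_stem, at_root = TRUE)
  membership <- list()
  groups <- list()
  gi <- 0L
  for (u in units) {
    gi <- gi + 1L
    gname <- sprintf("group_%02d", gi)
    orphan <- length(u$tips) == 1L
    # subgroups: same rule inside the group subtree with the smaller stem
    if (!orphan) {
      sub_tree_node <- ape::getMRCA(tree, u$tips)
      sub_units <- cut_units(sub_tree_node, min_stem_subgroup, at_root = TRUE)
      si <- 0L
      for (su in sub_units) {
        si <- si + 1L
        for (tp in su$tips) {
          membership[[length(membership) + 1L]] <- data.frame(
            taxon = tp, group = gname,
            subgroup = sprintf("%s_sg_%02d", gname, si),
            orphan = FALSE, stringsAsFactors = FALSE
          )
        }
      }
    } else {
      membership[[length(membership) + 1L]] <- data.frame(
        taxon = u$tips, group = gname, subgroup = paste0(gname, "_sg_01"),
        orphan = TRUE, stringsAsFactors = FALSE
      )
    }
    groups[[gname]] <- list(name = gname, members = u$tips, orphan = orphan)
  }
  structure(
    list(membership = do.call(rbind, membership), groups = groups,
         notes = notes),
    class = "group_partition"
  )
}

#' Name groups and subgroups after their earliest-described species
#'
#' Each group/subgroup is renamed "<earliest-described member> G" (or "SG").
#' Year ties are broken lexicographically; a group with no year among its
#' members keeps a placeholder name with a warning.
#'
#' @param partition A \code{group_partition}.
#' @param description_years Named numeric vector species -> description year.
#' @return The partition with names substituted in \code{membership} and
#'   \code{groups}.
#' @export
name_partition <- function(partition, description_years) {
  stopifnot(inherits(partition, "group_partition"))
  mem <- partition$membership
  pick <- function(members, suffix) {
    yrs <- description_years[members]
    if (all(is.na(yrs))) {
      warning("no description year among {",
              paste(members, collapse = ", "), "}; placeholder name kept")
      return(NA_character_)
    }
    best <- min(yrs, na.rm = TRUE)
    cand <- sort(members[!is.na(yrs) & yrs == best])
    paste(cand[1L], suffix)
  }
  for (g in unique(mem$group)) {
    nm <- pick(mem$taxon[mem$group == g], "G")
    if (!is.na(nm)) {
      partition$groups[[g]]$name <- nm
      mem$group[mem$group == g] <- nm
    }
  }
  for (sg in unique(mem$subgroup)) {
    nm <- pick(mem$taxon[mem$subgroup == sg], "SG")
    if (!is.na(nm)) mem$subgroup[mem$subgroup == sg] <- nm
  }
  partition$membership <- mem
  names(partition$groups) <- vapply(partition$groups, function(g) g$name,
                                    character(1L))
  partition
}

#' Write a group partition as a two-column TSV (taxon, group[/subgroup])
#' @param partition A \code{group_partition}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_partition_tsv <- function(partition, path) {
  mem <- partition$membership
  out <- data.frame(
    taxon = mem$taxon,
    group = ifelse(mem$subgroup == mem$group, mem$group,
                   paste0(mem$group, "/", mem$subgroup)),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
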