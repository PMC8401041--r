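#' Generate a synthetic NRPS gene-cluster architecture
#'
#' Emits a \code{\link{bgc_architecture}} with known ground truth. For CLP
#' families the per-gene module distribution follows the packaged family
#' reference table: chains of C-A-T elongation modules, a C-lacking (A-T)
#' initiation module on the first gene, the terminal module closed by two
#' consecutive TE domains, and no epimerization domains. \code{"novel"}
#' produces a valid CLP architecture matching no packaged family.
#' \code{"none"} produces a non-CLP NRPS (single TE, E domains present).
#' \code{fragmented = TRUE} emits a tandem-TE-bearing fragment without a
#' complete module chain (contig-edge situation).
#'
#' @param family_label One of \code{"Viscosin/WLIP"}, \code{"Putisolvin"},
#'   \code{"Entolysin"}, \code{"Xantholysin"}, \code{"LP-13"},
#'   \code{"novel"}, \code{"none"}.
#' @param fragmented Emit a fragmented architecture (putative evidence only).
#' @param seed Integer seed (fixes the cluster id suffix; the architecture
#'   itself is deterministic given the family).
#' @return A \code{\link{bgc_architecture}}.
#' @export
generate_bgc <- function(family_label, fragmented = FALSE, seed = 1L) {
  allowed <- c("Viscosin/WLIP", "Putisolvin", "Entolysin", "Xantholysin",
               "LP-13", "novel", "none")
  if (!family_label %in% allowed) {
    stop("unknown family label '", family_label, "'; expected one of: ",
         paste(allowed, collapse = ", "))
  }
  cid <- sprintf("synthetic_%s_s%d",
                 gsub("[^A-Za-z0-9]", "", family_label), as.integer(seed))
  if (fragmented) {
    # tandem-TE fragment: a truncated terminal gene only, no complete chain
    genes <- list(list(
      gene_id = "fragB", strand = "+",
      modules = list(c("T", "TE", "TE"))
    ))
    return(bgc_architecture(cid, genes, complete = FALSE))
  }
  if (family_label == "none") {
    # non-CLP NRPS: epimerization domains present, single terminal TE
    genes <- list(
      list(gene_id = "nrpsA", strand = "+",
           modules = list(c("A", "T"), c("C", "A", "T", "E"))),
      list(gene_id = "nrpsB", strand = "+",
           modules = list(c("C", "A", "T", "E"), c("C", "A", "T", "TE")))
    )
    return(bgc_architecture(cid, genes, complete = TRUE))
  }
  dist <- if (family_label == "novel") {
    c(2L, 4L, 4L) # 10 modules: matches no packaged family total
  } else {
    refs <- clp_family_reference()
    row <- refs[refs$family == family_label, ]
    as.integer(strsplit(row$per_gene_modules, ",")[[1L]])
  }
  genes <- vector("list", length(dist))
  for (gi in seq_along(dist)) {
    mods <- vector("list", dist[gi])
    for (mi in seq_len(dist[gi])) {
      first_module <- gi == 1L && mi == 1L
      last_module <- gi == length(dist) && mi == dist[gi]
      core <- if (first_module) c("A", "T") else c("C", "A", "T")
      if (last_module) core <- c(core, "TE", "TE")
      mods[[mi]] <- core
    }
    genes[[gi]] <- list(gene_id = sprintf("clpGene%d", gi), strand = "+",
                        modules = mods)
  }
  bgc_architecture(cid, genes, complete = TRUE)
}

#' Serialize a BGC architecture to the simplified domain-string TSV
#'
#' Writes lines \code{cluster_id<TAB>gene:strand:domains<TAB>complete} in the
#' dialect accepted by \code{\link{parse_bgc}}, so generated architectures
#' round-trip through the parser.
#'
#' @param archs A \code{bgc_architecture} or list of them.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bgc_tsv <- function(archs, path) {
  if (inherits(archs, "bgc_architecture")) archs <- list(archs)
  lines <- vapply(archs, function(a) {
    gene_str <- paste(vapply(a$genes, function(g) {
      mods <- paste(vapply(g$modules, paste, character(1L), collapse = "-"),
                    collapse = ",")
      paste(g$gene_id, g$strand, mods, sep = ":")
    }, character(1L)), collapse = ";")
    paste(a$cluster_id, gene_str, a$complete, sep = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
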