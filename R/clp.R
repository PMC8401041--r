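# Cyclic-lipopeptide (CLP) NRPS screening.
#
# Pseudomonas CLP assembly lines have a diagnostic architecture: modular
# NRPSs whose final module ends in two consecutive thioesterase (TE) domains,
# and no epimerization (E) domains anywhere (D-amino acids are installed by
# dual-function C/E condensation domains instead). Family assignment uses
# synteny only: total module count and the per-gene module distribution.

.DOMAIN_ALPHABET <- c("C", "A", "T", "TE", "E", "other")

# antiSMASH-style domain names -> normalized tokens
.normalize_domain <- function(x) {
  x0 <- toupper(trimws(x))
  if (x0 %in% c("C", "CONDENSATION", "CONDENSATION_START",
                "CONDENSATION_LCL", "CONDENSATION_DCL", "CONDENSATION_DUAL",
                "CSTART", "C/E", "CE")) return("C")
  if (x0 %in% c("A", "AMP-BINDING", "AMP_BINDING", "ADENYLATION")) return("A")
  if (x0 %in% c("T", "PCP", "PP-BINDING", "PP_BINDING", "THIOLATION",
                "CARRIER")) return("T")
  if (x0 %in% c("TE", "THIOESTERASE", "TD")) return("TE")
  if (x0 %in% c("E", "EPIMERIZATION", "EPIMERASE")) return("E")
  if (x0 %in% toupper(.DOMAIN_ALPHABET)) return("other")
  warning("unknown domain token '", x, "' normalized to 'other'")
  "other"
}

#' Construct a BGC architecture
#'
#' @param cluster_id Cluster identifier.
#' @param genes List of gene entries, each a list with \code{gene_id},
#'   \code{strand}, and \code{modules} (list of character vectors of domain
#'   tokens from \{C, A, T, TE, E, other\}).
#' @param complete \code{FALSE} when the cluster sits on a contig edge or is
#'   otherwise fragmented.
#' @return An object of class \code{bgc_architecture}.
#' @export
bgc_architecture <- function(cluster_id, genes, complete = TRUE) {
  for (g in genes) {
    stopifnot(is.character(g$gene_id), g$strand %in% c("+", "-"))
    for (mod in g$modules) {
      bad <- setdiff(mod, .DOMAIN_ALPHABET)
      if (length(bad)) {
        stop("unknown domain token(s) in ", g$gene_id, ": ",
             paste(bad, collapse = ", "))
      }
    }
  }
  structure(list(cluster_id = cluster_id, genes = genes, complete = complete),
            class = "bgc_architecture")
}

#' Parse BGC annotation documents
#'
#' Two dialects are supported. The simplified domain-string TSV has lines
#' \code{cluster_id<TAB>geneA:+:C-A-T,C-A-T;geneB:+:C-A-T-TE-TE} (modules
#' comma-separated, genes semicolon-separated, domains hyphen-separated; an
#' optional third column \code{complete} holds TRUE/FALSE). The JSON dialect
#' follows the antiSMASH v6 layout: top-level \code{records}, each with
#' \code{id}, optional \code{contig_edge}, and \code{features} of type
#' \code{"aSDomain"} carrying \code{locus_tag}, \code{strand} and
#' \code{domain} qualifiers in gene order. Domain names are normalized
#' (thiolation/PCP -> T); unknown tokens warn and become \code{other}.
#'
#' @param path Path to a \code{.tsv}/\code{.txt} or \code{.json} document.
#' @return A list of \code{\link{bgc_architecture}} objects (possibly empty).
#' @export
parse_bgc <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    .parse_bgc_json(path)
  } else {
    .parse_bgc_tsv(path)
  }
}

.parse_bgc_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 2L) {
      stop("malformed BGC TSV line (need cluster_id<TAB>genes): ", ln)
    }
    cluster_id <- parts[1L]
    complete <- if (length(parts) >= 3L) as.logical(parts[3L]) else TRUE
    gene_specs <- strsplit(parts[2L], ";", fixed = TRUE)[[1L]]
    genes <- lapply(gene_specs, function(gs) {
      fields <- strsplit(gs, ":", fixed = TRUE)[[1L]]
      if (length(fields) != 3L) {
        stop("malformed gene spec '", gs, "' (need id:strand:domains)")
      }
      modules <- lapply(strsplit(fields[3L], ",", fixed = TRUE)[[1L]],
                        function(m) {
                          vapply(strsplit(m, "-", fixed = TRUE)[[1L]],
                                 .normalize_domain, character(1L),
                                 USE.NAMES = FALSE)
                        })
      list(gene_id = fields[1L], strand = fields[2L], modules = modules)
    })
    out[[length(out) + 1L]] <- bgc_architecture(cluster_id, genes, complete)
  }
  out
}

.parse_bgc_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$records)) stop("invalid BGC JSON: no 'records' field")
  out <- list()
  for (rec in doc$records) {
    feats <- rec$features
    if (is.null(feats)) feats <- list()
    dom_feats <- Filter(function(f) identical(f$type, "aSDomain"), feats)
    if (length(dom_feats) == 0L) next
    per_gene <- list()
    order_seen <- character(0)
    for (f in dom_feats) {
      q <- f$qualifiers
      gene <- q$locus_tag[[1L]]
      strand <- if (is.null(q$strand)) "+" else q$strand[[1L]]
      dom <- .normalize_domain(q$domain[[1L]])
      if (!gene %in% order_seen) {
        order_seen <- c(order_seen, gene)
        per_gene[[gene]] <- list(strand = strand, domains = character(0))
      }
      per_gene[[gene]]$domains <- c(per_gene[[gene]]$domains, dom)
    }
    genes <- lapply(order_seen, function(g) {
      list(gene_id = g, strand = per_gene[[g]]$strand,
           modules = .segment_modules(per_gene[[g]]$domains))
    })
    complete <- !isTRUE(rec$contig_edge)
    out[[length(out) + 1L]] <- bgc_architecture(rec$id, genes, complete)
  }
  out
}

# Segment a flat domain stream into modules: a new module starts at each C,
# or at an A when the running module already holds an A (initiation modules
# may lack C).
.segment_modules <- function(domains) {
  modules <- list()
  current <- character(0)
  for (d in domains) {
    starts_new <- (d == "C" && length(current) > 0L) ||
      (d == "A" && "A" %in% current)
    if (starts_new) {
      modules[[length(modules) + 1L]] <- current
      current <- character(0)
    }
    current <- c(current, d)
  }
  if (length(current)) modules[[length(modules) + 1L]] <- current
  modules
}

# A module counts when it carries an A-T core (leading C optional); this
# matches published family totals, which include C-lacking initiation
# modules.
.is_counted_module <- function(mod) {
  a <- match("A", mod)
  t <- match("T", mod)
  !is.na(a) && !is.na(t) && t > a
}

#' Detect a CLP-type NRPS architecture
#'
#' Diagnostic rule: tandem TE domains (>= 2 consecutive TEs closing the final
#' module) and no epimerization domain anywhere. A complete architecture
#' passing both tests is \code{positive}; an incomplete (fragmented) one with
#' tandem TEs and no E domain is \code{putative}; everything else is
#' \code{negative}.
#'
#' @param arch A \code{\link{bgc_architecture}}.
#' @return An object of class \code{clp_call}: \code{cluster_id},
#'   \code{status}, \code{total_modules}, \code{per_gene_modules},
#'   \code{tandem_te}, \code{has_e_domain}, \code{complete}, \code{family}
#'   (\code{"unassigned"} until \code{\link{assign_family}}).
#' @export
detect_clp <- function(arch) {
  stopifnot(inherits(arch, "bgc_architecture"))
  all_domains <- unlist(lapply(arch$genes, function(g) unlist(g$modules)))
  has_e <- "E" %in% all_domains
  tandem_te <- FALSE
  if (length(arch$genes)) {
    last_gene <- arch$genes[[length(arch$genes)]]
    if (length(last_gene$modules)) {
      last_mod <- last_gene$modules[[length(last_gene$modules)]]
      n <- length(last_mod)
      tandem_te <- n >= 2L && last_mod[n] == "TE" && last_mod[n - 1L] == "TE"
    }
  }
  per_gene <- vapply(arch$genes, function(g) {
    sum(vapply(g$modules, .is_counted_module, logical(1L)))
  }, integer(1L))
  status <- if (tandem_te && !has_e) {
    if (arch$complete) "positive" else "putative"
  } else {
    "negative"
  }
  structure(
    list(cluster_id = arch$cluster_id, status = status,
         total_modules = sum(per_gene), per_gene_modules = unname(per_gene),
         tandem_te = tandem_te, has_e_domain = has_e,
         complete = arch$complete, family = "unassigned", family_note = ""),
    class = "clp_call"
  )
}

#' @export
print.clp_call <- function(x, ...) {
  cat(sprintf("<clp_call> %s: %s, %d modules (%s), family %s\n",
              x$cluster_id, x$status, x$total_modules,
              paste(x$per_gene_modules, collapse = "+"), x$family))
  invisible(x)
}

#' Load the packaged CLP family reference table
#'
#' Per-family total module counts and per-gene module distributions, curated
#' from the CLP literature (the LP-13 and N8 rows are provisional stubs).
#' The table is plain data and can be replaced without code changes.
#'
#' @param path Optional path to an alternative reference TSV.
#' @return data.frame with columns \code{family}, \code{total_modules},
#'   \code{per_gene_modules} (comma-separated), \code{notes}.
#' @export
clp_family_reference <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "clp_family_reference.tsv",
                        package = "pseudotax")
  }
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Assign a positive CLP call to a family by synteny
#'
#' A unique reference matching both the total module count and the exact
#' per-gene distribution wins; a total-only match is reported with a
#' "distribution-mismatch" note; no match at all yields \code{"novel"}.
#' Multiple exact matches raise an ambiguity error.
#'
#' @param call A \code{clp_call} with status \code{"positive"}.
#' @param references Family reference table
#'   (\code{\link{clp_family_reference}}).
#' @return The call with \code{family} (and possibly \code{family_note})
#'   filled.
#' @export
assign_family <- function(call, references = clp_family_reference()) {
  stopifnot(inherits(call, "clp_call"))
  if (call$status != "positive") {
    stop("assign_family requires a positive CLP call (got '",
         call$status, "')")
  }
  ref_dists <- lapply(strsplit(references$per_gene_modules, ","),
                      as.integer)
  exact <- which(references$total_modules == call$total_modules &
                   vapply(ref_dists, function(d) {
                     length(d) == length(call$per_gene_modules) &&
                       all(d == call$per_gene_modules)
                   }, logical(1L)))
  if (length(exact) > 1L) {
    stop("ambiguous family assignment; exact matches: ",
         paste(references$family[exact], collapse = ", "))
  }
  if (length(exact) == 1L) {
    call$family <- references$family[exact]
    return(call)
  }
  total_only <- which(references$total_modules == call$total_modules)
  if (length(total_only) == 1L) {
    call$family <- references$family[total_only]
    call$family_note <- "distribution-mismatch"
    return(call)
  }
  if (length(total_only) > 1L) {
    call$family <- "unassigned"
    call$family_note <- paste0(
      "total-module count matches several families (",
      paste(references$family[total_only], collapse = ", "),
      ") but no per-gene distribution matches"
    )
    return(call)
  }
  call$family <- "novel"
  call
}

#' Single-linkage clustering of producers by NRPS sequence identity
#'
#' Pairwise global identity of concatenated NRPS amino-acid sequences,
#' followed by single-linkage clustering at the given identity threshold.
#' On family-structured panels the clusters coincide with family labels.
#'
#' @param sequences Named character vector producer -> concatenated NRPS
#'   amino-acid sequence (>= 2 producers, none empty).
#' @param linkage_threshold Identity percent at or above which two producers
#'   are linked.
#' @return A list: \code{clusters} (named integer vector), \code{identity}
#'   (symmetric percent matrix).
#' @export
nrps_similarity_clusters <- function(sequences, linkage_threshold = 70) {
  if (length(sequences) < 2L) stop("need at least 2 producers")
  if (any(!nzchar(sequences))) stop("empty NRPS sequence supplied")
  ids <- names(sequences)
  if (is.null(ids)) stop("sequences must be named by producer")
  n <- length(ids)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(sequences[[i]]),
        Biostrings::AAString(sequences[[j]]),
        type = "global", substitutionMatrix = "BLOSUM62",
        gapOpening = 10, gapExtension = 0.5
      )
      p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
      s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
      v <- 100 * sum(p == s & p != "-") / length(p)
      m[i, j] <- m[j, i] <- v
    }
  }
  clusters <- .single_linkage(ids, m, linkage_threshold)
  list(clusters = clusters, identity = m)
}

#' Write CLP calls as a report TSV
#' @param calls List of \code{clp_call}s.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_clp_report_tsv <- function(calls, path) {
  rows <- lapply(calls, function(x) data.frame(
    cluster_id = x$cluster_id, status = x$status,
    total_modules = x$total_modules,
    per_gene_modules = paste(x$per_gene_modules, collapse = ","),
    tandem_te = x$tandem_te, has_e_domain = x$has_e_domain,
    complete = x$complete, family = x$family, note = x$family_note,
    stringsAsFactors = FALSE
  ))
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
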