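test_that("the TSV dialect parses gene, module and completeness structure", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "clusterX\tgeneA:+:C-A-T,C-A-T;geneB:+:C-A-T-TE-TE",
    "edgeY\tgeneC:+:C-A-T-TE-TE\tFALSE"
  ), tmp)
  archs <- parse_bgc(tmp)
  expect_length(archs, 2L)
  a <- archs[[1L]]
  expect_length(a$genes, 2L)
  expect_equal(sum(lengths(lapply(a$genes, `[[`, "modules"))), 3L)
  expect_true(a$complete)
  expect_false(archs[[2L]]$complete)
  call <- detect_clp(a)
  expect_true(call$tandem_te)
  expect_equal(call$total_modules, 3L)

  # unknown tokens warn and normalize to "other"
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("c1\tg:+:C-A-T-FOO-TE-TE", tmp2)
  expect_warning(a2 <- parse_bgc(tmp2), "unknown domain")
  expect_true("other" %in% unlist(a2[[1L]]$genes[[1L]]$modules))

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_length(parse_bgc(empty), 0L)
  expect_error(parse_bgc(withr::local_tempfile()), "no such file")

  tmp3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("only_one_field", tmp3)
  expect_error(parse_bgc(tmp3), "malformed")
})

test_that("the antiSMASH-style JSON dialect parses with contig-edge flags", {
  tmp <- withr::local_tempfile(fileext = ".json")
  doc <- list(records = list(
    list(
      id = "region1", contig_edge = FALSE,
      features = list(
        list(type = "aSDomain",
             qualifiers = list(locus_tag = list("g1"), strand = list("+"),
                               domain = list("AMP-binding"))),
        list(type = "aSDomain",
             qualifiers = list(locus_tag = list("g1"), strand = list("+"),
                               domain = list("PCP"))),
        list(type = "aSDomain",
             qualifiers = list(locus_tag = list("g2"), strand = list("+"),
                               domain = list("Condensation_LCL"))),
        list(type = "aSDomain",
             qualifiers = list(locus_tag = list("g2"), strand = list("+"),
                               domain = list("AMP-binding"))),
        list(type = "aSDomain",
             qualifiers = list(locus_tag = list("g2"), strand = list("+"),
                               domain = list("PCP"))),
        list(type = "aSDomain",
             qualifiers = list(locus_tag = list("g2"), strand = list("+"),
                               domain = list("Thioesterase"))),
        list(type = "aSDomain",
             qualifiers = list(locus_tag = list("g2"), strand = list("+"),
                               domain = list("Thioesterase")))
      )
    ),
    list(id = "region2", contig_edge = TRUE,
         features = list(
           list(type = "aSDomain",
                qualifiers = list(locus_tag = list("g3"), strand = list("+"),
                                  domain = list("Thioesterase"))),
           list(type = "aSDomain",
                qualifiers = list(locus_tag = list("g3"), strand = list("+"),
                                  domain = list("Thioesterase")))
         ))
  ))
  jsonlite::write_json(doc, tmp, auto_unbox = TRUE)
  archs <- parse_bgc(tmp)
  expect_length(archs, 2L)
  c1 <- detect_clp(archs[[1L]])
  expect_identical(c1$status, "positive")
  expect_equal(c1$total_modules, 2L)
  c2 <- detect_clp(archs[[2L]])
  expect_identical(c2$status, "putative")

  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(nothing = 1), bad, auto_unbox = TRUE)
  expect_error(parse_bgc(bad), "no 'records'")
})

test_that("CLP status is a pure function of tandem-TE, E-domain, completeness", {
  make_arch <- function(tandem_te, has_e, complete) {
    tail_domains <- if (tandem_te) c("C", "A", "T", "TE", "TE") else
      c("C", "A", "T", "TE")
    mods <- list(c("A", "T", if (has_e) "E"), tail_domains)
    bgc_architecture("combo", list(
      list(gene_id = "g", strand = "+", modules = mods)
    ), complete = complete)
  }
  cases <- expand.grid(tandem_te = c(TRUE, FALSE), has_e = c(TRUE, FALSE),
                       complete = c(TRUE, FALSE))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    call <- detect_clp(make_arch(cs$tandem_te, cs$has_e, cs$complete))
    expected <- if (cs$tandem_te && !cs$has_e) {
      if (cs$complete) "positive" else "putative"
    } else {
      "negative"
    }
    expect_identical(call$status, expected)
    expect_equal(call$tandem_te, cs$tandem_te)
    expect_equal(call$has_e_domain, cs$has_e)
  }
})

test_that("generate -> detect -> assign returns the generating family", {
  for (fam in c("Viscosin/WLIP", "Putisolvin", "Entolysin", "Xantholysin",
                "LP-13")) {
    arch <- generate_bgc(fam)
    call <- detect_clp(arch)
    expect_identical(call$status, "positive")
    expect_false(call$has_e_domain)
    assigned <- assign_family(call)
    expect_identical(assigned$family, fam)
    expect_identical(assigned$family_note, "")
  }
  expect_equal(detect_clp(generate_bgc("Putisolvin"))$total_modules, 12L)

  novel <- assign_family(detect_clp(generate_bgc("novel")))
  expect_identical(novel$family, "novel")

  none <- detect_clp(generate_bgc("none"))
  expect_identical(none$status, "negative")
  expect_true(none$has_e_domain)

  frag <- detect_clp(generate_bgc("Putisolvin", fragmented = TRUE))
  expect_identical(frag$status, "putative")
  expect_error(assign_family(frag), "positive")
})

test_that("family assignment distinguishes synteny from totals", {
  refs <- clp_family_reference()
  # same total as Xantholysin/Entolysin (14) but matching neither distribution
  arch <- bgc_architecture("x14", list(
    list(gene_id = "g1", strand = "+",
         modules = c(list(c("A", "T")), rep(list(c("C", "A", "T")), 12L),
                     list(c("C", "A", "T", "TE", "TE"))))
  ), complete = TRUE)
  call <- detect_clp(arch)
  expect_equal(call$total_modules, 14L)
  out <- assign_family(call, refs)
  expect_identical(out$family, "unassigned")
  expect_match(out$family_note, "several families")

  # unique total (13) with a different distribution -> LP-13 with a note
  arch13 <- bgc_architecture("x13", list(
    list(gene_id = "g1", strand = "+",
         modules = c(list(c("A", "T")), rep(list(c("C", "A", "T")), 11L),
                     list(c("C", "A", "T", "TE", "TE"))))
  ), complete = TRUE)
  out13 <- assign_family(detect_clp(arch13), refs)
  expect_identical(out13$family, "LP-13")
  expect_identical(out13$family_note, "distribution-mismatch")

  # duplicated exact references raise an ambiguity error
  dup <- rbind(refs, refs[refs$family == "Putisolvin", ])
  dup$family[nrow(dup)] <- "Putisolvin-bis"
  expect_error(assign_family(detect_clp(generate_bgc("Putisolvin")), dup),
               "ambiguous")
})

test_that("generated architectures round-trip through the TSV writer", {
  archs <- lapply(c("Putisolvin", "Xantholysin"), generate_bgc)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_bgc_tsv(archs, tmp)
  back <- parse_bgc(tmp)
  expect_length(back, 2L)
  for (i in 1:2) {
    expect_identical(detect_clp(back[[i]])$per_gene_modules,
                     detect_clp(archs[[i]])$per_gene_modules)
  }
})

test_that("NRPS similarity clusters recover family structure", {
  set.seed(6)
  aa <- function(n) paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]],
                                 n, TRUE), collapse = "")
  mut_aa <- function(s, rate) {
    ch <- strsplit(s, "")[[1L]]
    pos <- which(runif(length(ch)) < rate)
    alpha <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
    for (p in pos) ch[p] <- sample(setdiff(alpha, ch[p]), 1L)
    paste(ch, collapse = "")
  }
  famA <- aa(400); famB <- aa(400)
  seqs <- c(p1 = mut_aa(famA, 0.05), p2 = mut_aa(famA, 0.05),
            p3 = mut_aa(famB, 0.05), p4 = mut_aa(famB, 0.05))
  res <- nrps_similarity_clusters(seqs, linkage_threshold = 70)
  expect_true(same_partition(res$clusters, c(1, 1, 2, 2)))
  expect_equal(res$identity["p1", "p1"], 100)

  same <- nrps_similarity_clusters(c(a = famA, b = famA))
  expect_equal(same$identity["a", "b"], 100)
  expect_error(nrps_similarity_clusters(c(a = famA)), "at least 2")
  expect_error(nrps_similarity_clusters(c(a = famA, b = "")), "empty")
})
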