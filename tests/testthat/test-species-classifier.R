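test_that("the decision tree reproduces the published worked examples", {
  # assigned outright above the species cutoff
  a1 <- assign_species("02C-26", "P. shirazensis", 97.25)
  expect_identical(a1$decision, "ASSIGNED")
  # ambiguity zone with a dDDH-below-70 flag -> new species
  a2 <- assign_species("250J", "P. peradeniyensis", 96.15,
                       ddh = ddh_flag(c("250J", "P. peradeniyensis"), TRUE))
  expect_identical(a2$decision, "NEW-SPECIES")
  # ambiguity zone resolved by supplied dDDH >= 70
  a3 <- assign_species("MX-2", "P. alloputida", 96.49,
                       ddh = ddh_for_pair(c("MX-2", "P. alloputida"),
                                          supplied = 72))
  expect_identical(a3$decision, "ASSIGNED-VIA-DDH")
  expect_true(nrow(a3$rule_trace) >= 2L)
})

test_that("interval boundaries are inclusive on the left", {
  expect_identical(assign_species("s", "t", 96.5)$decision, "ASSIGNED")
  amb <- assign_species("s", "t", 95.0)
  expect_identical(amb$decision, "AMBIGUOUS-UNRESOLVED")
  expect_identical(assign_species("s", "t", 94.999)$decision, "NEW-SPECIES")
  expect_error(assign_species("s", "t", NA_real_), "undefined ANI")
})

test_that("every strain gets exactly one decision and a reconstructable trace", {
  set.seed(1)
  for (ani in runif(25, 85, 100)) {
    ddh <- if (ani >= 95 && ani < 96.5) {
      ddh_for_pair(c("q", "t"), supplied = runif(1, 50, 90))
    } else {
      NULL
    }
    a <- assign_species("q", "t", ani, ddh)
    expect_true(a$decision %in% c("ASSIGNED", "ASSIGNED-VIA-DDH",
                                  "NEW-SPECIES", "AMBIGUOUS-UNRESOLVED"))
    expect_gt(nrow(a$rule_trace), 0L)
    # trace outcome of the last consulted rule matches the decision
    expect_identical(a$rule_trace$outcome[nrow(a$rule_trace)], a$decision)
  }
})

test_that("synonym collapse follows single linkage with year priority", {
  ids <- c("P. veronii", "P. panacis", "P. lonely")
  m <- matrix(0, 3, 3, dimnames = list(ids, ids))
  diag(m) <- 100
  m["P. veronii", "P. panacis"] <- m["P. panacis", "P. veronii"] <- 99.95
  yrs <- c("P. veronii" = 1996, "P. panacis" = 2005, "P. lonely" = 2000)
  cl <- collapse_synonyms(ids, m, yrs)
  expect_length(cl, 1L)
  expect_setequal(cl[[1L]]$members, c("P. veronii", "P. panacis"))
  expect_identical(cl[[1L]]$representative, "P. veronii")

  # all below threshold -> empty output
  m2 <- m; m2["P. veronii", "P. panacis"] <- m2["P. panacis", "P. veronii"] <- 90
  expect_length(collapse_synonyms(ids, m2, yrs), 0L)

  # order invariance
  cl_rev <- collapse_synonyms(rev(ids), m, yrs)
  expect_setequal(cl_rev[[1L]]$members, cl[[1L]]$members)

  # missing years fall back to a lexicographic representative with a warning
  expect_warning(
    cl3 <- collapse_synonyms(ids, m, numeric(0)),
    "lexicographically"
  )
  expect_identical(cl3[[1L]]$representative, "P. panacis")
})

test_that("new-species clustering equals brute-force transitive closure", {
  set.seed(2)
  ids <- sprintf("strain%02d", 1:12)
  m <- matrix(runif(144, 90, 99), 12, 12, dimnames = list(ids, ids))
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 100
  assignments <- lapply(ids, function(s) assign_species(s, "type", 90))
  got <- cluster_new_species(assignments, m)
  nums <- vapply(got, function(a) a$new_species_number, integer(1L))
  expect_true(same_partition(nums, closure_clusters(ids, m, 96.5)))
  expect_false(anyNA(nums))

  # mutually linked pair shares a number; distant strains get their own
  two <- matrix(c(100, 97, 97, 100), 2, 2,
                dimnames = list(c("NX-1", "PC2"), c("NX-1", "PC2")))
  pair <- cluster_new_species(
    lapply(c("NX-1", "PC2"), function(s) assign_species(s, "t", 94.7)), two
  )
  expect_equal(pair[[1L]]$new_species_number, pair[[2L]]$new_species_number)

  # missing pair in the matrix is an error
  m_na <- m; m_na[1L, 2L] <- m_na[2L, 1L] <- NA
  expect_error(cluster_new_species(assignments, m_na), "missing")
  expect_error(
    cluster_new_species(list(assign_species("s", "t", 99)), m),
    "NEW-SPECIES"
  )
})

test_that("fixture validation reports offending rows", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "section\tgroup\tsubgroup\tspecies\tn_species\trpod_range\tanib_range",
    "existing\tG1\t\tP. a;P. b\t3\t-\t-"
  ), tmp)
  expect_error(parse_fixture(tmp, "table1"), "row 1")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("section\tgroup\tsubgroup\tspecies\tn_species\trpod_range\tanib_range",
             empty)
  expect_error(parse_fixture(empty, "table1"), "empty")
  expect_error(parse_fixture("/nonexistent/file.tsv", "table1"), "no such")
})
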