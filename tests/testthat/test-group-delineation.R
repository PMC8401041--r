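test_that("NJ reproduces additive quartets exactly", {
  set.seed(1)
  for (i in 1:10) {
    q <- random_additive_quartet()
    tr <- nj_tree(q$D)
    # tree metric must equal the input distances (additive recovery)
    coph <- ape::cophenetic.phylo(tr)[rownames(q$D), colnames(q$D)]
    expect_lt(max(abs(coph - q$D)), 1e-9)
    # topology agrees with the least-squares brute force
    expect_identical(quartet_sisters(tr), ls_quartet_oracle(q$D)$sisters)
  }
})

test_that("NJ handles the 3-taxon cherry and rejects bad input", {
  D <- matrix(c(0, 1, 6, 1, 0, 6, 6, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  coph <- ape::cophenetic.phylo(tr)
  expect_lt(coph["A", "B"], coph["A", "C"])

  expect_error(nj_tree(D[1:2, 1:2]), "at least 3")
  D_bad <- D; D_bad[1, 2] <- 3
  expect_error(nj_tree(D_bad), "symmetric")
})

test_that("bootstrap supports separate planted clades and are deterministic", {
  set.seed(2)
  rootseq <- random_dna(650)
  ancA <- mutate_k(rootseq, 55)
  ancB <- mutate_k(rootseq, 55)
  seqs <- c(
    a1 = mutate_k(ancA, 5), a2 = mutate_k(ancA, 5), a3 = mutate_k(ancA, 5),
    b1 = mutate_k(ancB, 5), b2 = mutate_k(ancB, 5), b3 = mutate_k(ancB, 5)
  )
  bs <- bootstrap_supports(seqs, n_replicates = 200, seed = 7)
  bs2 <- bootstrap_supports(seqs, n_replicates = 200, seed = 7)
  expect_identical(bs$supports, bs2$supports)
  # the clade containing {a1,a2,a3} (equivalently {b1,b2,b3}) is near-certain
  part <- ape::prop.part(bs$tree)
  labs <- attr(part, "labels")
  clade_support <- function(tips) {
    target <- sort(match(tips, labs))
    for (n in seq_along(bs$supports)) {
      node <- length(labs) + n
      desc <- ape::extract.clade(bs$tree, node)$tip.label
      side <- sort(match(desc, labs))
      if (identical(side, target) ||
            identical(side, sort(setdiff(seq_along(labs), target)))) {
        return(bs$supports[n])
      }
    }
    NA_real_
  }
  expect_gte(clade_support(c("a1", "a2", "a3")), 95)

  # permuted taxon order gives identical supports
  bs_perm <- bootstrap_supports(seqs[c(4, 2, 6, 1, 3, 5)],
                                n_replicates = 200, seed = 7)
  expect_identical(bs_perm$supports, bs$supports)

  # a single replicate can only give 0 or 100
  one <- bootstrap_supports(seqs, n_replicates = 1, seed = 3)
  expect_true(all(one$supports %in% c(0, 100)))
})

test_that("delineation cuts supported clades and orphans the rest", {
  # three distant taxa under an unsupported root: all orphans
  star <- ape::read.tree(text = "((A:5,B:5)20:1,C:5);")
  p <- delineate(star, min_stem = 1)
  expect_equal(length(p$groups), 3L)
  expect_true(all(vapply(p$groups, function(g) g$orphan, logical(1L))))

  # two supported clades become two groups matching the planted labels
  two <- ape::read.tree(text = "((A:1,B:1)95:3,(C:1,D:1)99:3);")
  p2 <- delineate(two, min_stem = 1)
  expect_equal(length(p2$groups), 2L)
  members <- lapply(p2$groups, function(g) sort(g$members))
  expect_true(list(c("A", "B")) %in% members && list(c("C", "D")) %in% members)

  # partition property: every leaf in exactly one group and one subgroup
  mem <- p2$membership
  expect_setequal(mem$taxon, two$tip.label)
  expect_equal(anyDuplicated(mem$taxon), 0L)

  # outgroup rooting drops the outgroup from the partition
  og <- ape::read.tree(text = "(((A:1,B:1)95:3,(C:1,D:1)99:3)90:2,OUT:10);")
  p3 <- delineate(og, min_stem = 1, outgroup = "OUT")
  expect_false("OUT" %in% p3$membership$taxon)
  expect_error(delineate(og, outgroup = "nope"), "not a tree tip")
})

test_that("raising the support cutoff never adds multi-member groups", {
  tr <- ape::read.tree(
    text = "(((A:1,B:1)75:2,(C:1,D:1)85:2)60:1,(E:1,F:1)95:2);"
  )
  n_multi <- function(sup) {
    p <- delineate(tr, thresholds(group_support = sup), min_stem = 1)
    sum(vapply(p$groups, function(g) length(g$members) > 1L, logical(1L)))
  }
  counts <- vapply(c(70, 80, 90, 99), n_multi, numeric(1L))
  expect_true(all(diff(counts) <= 0))
})

test_that("groups are named after their earliest-described member", {
  # newick labels cannot hold spaces; dot-joined binomials stand in
  tr <- ape::read.tree(text = paste0(
    "((P.entomophila:1,P.mosselii:1)95:3,",
    "(P.soli:1,P.sichuanensis:1)99:3);"
  ))
  p <- delineate(tr, min_stem = 1)
  yrs <- c("P.mosselii" = 2002, "P.entomophila" = 2006,
           "P.soli" = 2013, "P.sichuanensis" = 2019)
  named <- name_partition(p, yrs)
  expect_true("P.mosselii G" %in% names(named$groups))
  expect_true("P.soli G" %in% names(named$groups))
  # subgroup naming: singletons take their own member's name
  expect_true(all(c("P.entomophila SG", "P.mosselii SG") %in%
                    named$membership$subgroup))
  # tie in years -> lexicographic
  tie <- name_partition(p, c("P.mosselii" = 2002, "P.entomophila" = 2002,
                             "P.soli" = 2013, "P.sichuanensis" = 2013))
  expect_true("P.entomophila G" %in% names(tie$groups))
  w <- capture_warnings(name_partition(p, c("P.soli" = 2013)))
  expect_match(w, "placeholder", all = FALSE)
})
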