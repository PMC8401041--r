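test_that("fragmentation tiles contigs and applies the 100-bp tail rule", {
  set.seed(1)
  g <- genome_record("g", random_dna(5100))
  fr <- fragment_genome(g, 1020)
  expect_equal(nrow(fr), 5L)
  expect_equal(fr$end[5L], 5100)
  expect_true(all(fr$end - fr$start == 1020))

  g2 <- genome_record("g2", random_dna(1050))
  fr2 <- fragment_genome(g2, 1020)
  expect_equal(nrow(fr2), 1L)
  expect_equal(fr2$end[1L] - fr2$start[1L], 1020)

  g3 <- genome_record("g3", c(c1 = random_dna(2040), c2 = random_dna(2040)))
  fr3 <- fragment_genome(g3, 1020)
  expect_equal(nrow(fr3), 4L)
  expect_equal(fr3$parent_id, c("c1", "c1", "c2", "c2"))
  expect_equal(fr3$start, c(0L, 1020L, 0L, 1020L))

  # a 150-bp tail is retained
  g4 <- genome_record("g4", random_dna(1170))
  expect_equal(nrow(fragment_genome(g4, 1020)), 2L)

  expect_error(genome_record("empty", ""), "empty")
})

test_that("best_local_hit finds exact and reverse-complement containments", {
  set.seed(2)
  ref_seq <- random_dna(8000)
  frag <- substr(ref_seq, 3001, 4020)
  ref <- genome_record("ref", ref_seq)
  hit <- best_local_hit(frag, ref)
  expect_equal(hit$identity, 100)
  expect_equal(hit$coverage, 1)
  expect_identical(hit$strand, "+")
  expect_equal(hit$ref_start, 3000)
  expect_equal(hit$ref_end, 4020)

  rc_ref <- genome_record("rc", revcomp(ref_seq))
  hit_rc <- best_local_hit(frag, rc_ref)
  expect_equal(hit_rc$identity, 100)
  expect_identical(hit_rc$strand, "-")

  expect_error(best_local_hit(substr(frag, 1, 50), ref), ">= 100")
})

test_that("unrelated sequences never yield a usable fragment hit", {
  set.seed(3)
  frag <- random_dna(1020, gc = 0.5)
  th <- thresholds()
  usable <- 0L
  for (i in 1:100) {
    ref <- genome_record("r", random_dna(2000, gc = 0.5))
    hit <- best_local_hit(frag, ref)
    if (!is.null(hit) && hit$identity >= th$min_hit_identity &&
          hit$coverage >= th$min_hit_coverage) {
      usable <- usable + 1L
    }
  }
  expect_equal(usable, 0L)
})

test_that("ANIb matches the Hamming oracle on an indel-free pair", {
  anc <- simulate_ancestor(12240, 0.6, seed = 5)
  ev <- evolve_genome(anc, 0.02, 0, seed = 6, id = "mut")
  g0 <- genome_record("anc", anc$sequence)
  r <- anib_pairwise(g0, ev$genome)
  ham <- hamming_identity(anc$sequence, ev$genome$contigs[[1L]])
  expect_lt(abs(r$ani - ham), 0.5)
  expect_equal(r$aligned_fraction, 1)

  self <- anib_pairwise(g0, g0)
  expect_equal(self$ani, 100)
  expect_equal(self$aligned_fraction, 1)
  expect_false(self$undefined)
})

test_that("unrelated genomes give an undefined ANI flag, not zero", {
  set.seed(7)
  a <- genome_record("a", random_dna(12240))
  b <- genome_record("b", random_dna(12240))
  r <- anib_pairwise(a, b)
  expect_true(r$undefined)
  expect_true(is.na(r$ani))
  expect_equal(r$n_fragments_used, 0L)
})

test_that("the symmetric ANI summary is order-invariant with a 100 diagonal", {
  set.seed(8)
  seqs <- random_dna(10200)
  g <- list(genome_record("x", seqs), genome_record("y", seqs),
            genome_record("z", seqs))
  am <- ani_matrix(g)
  expect_true(all(am$symmetric == 100))
  am_rev <- ani_matrix(rev(g))
  expect_equal(am_rev$symmetric[c("x", "y", "z"), c("x", "y", "z")],
               am$symmetric)
  expect_error(ani_matrix(g[1L]), "at least 2")
})

test_that("the dDDH surrogate is calibrated, monotone, and labelled", {
  expect_equal(ddh_for_pair(c("a", "b"), symmetric_ani = 100)$value, 100)
  expect_equal(ddh_for_pair(c("a", "b"), symmetric_ani = 96.5)$value, 70)
  expect_equal(ddh_for_pair(c("a", "b"), symmetric_ani = 95)$value, 60)
  expect_identical(ddh_for_pair(c("a", "b"), symmetric_ani = 97)$source,
                   "surrogate")
  grid <- seq(80, 100, by = 0.25)
  vals <- vapply(grid, function(a) {
    ddh_for_pair(c("a", "b"), symmetric_ani = a)$value
  }, numeric(1L))
  expect_true(all(diff(vals) >= 0))
  expect_true(all(vals >= 0 & vals <= 100))

  sup <- ddh_for_pair(c("a", "b"), supplied = 42)
  expect_identical(sup$source, "supplied")
  expect_true(sup$below_threshold)
  flagged <- ddh_for_pair(c("a", "b"), supplied_below_threshold = TRUE)
  expect_true(flagged$below_threshold)
  expect_true(is.na(flagged$value))
  expect_error(ddh_for_pair(c("a", "b")), "neither")
})

test_that("ANI TSV reports round-trip through read.delim", {
  set.seed(9)
  s <- random_dna(10200)
  g <- list(genome_record("g1", s), genome_record("g2", mutate_k(s, 100)))
  am <- ani_matrix(g)
  dir <- withr::local_tempdir()
  write_ani_tsv(am, dir)
  sym <- read.delim(file.path(dir, "ani_symmetric.tsv"), check.names = FALSE)
  expect_equal(sym$id, c("g1", "g2"))
  expect_equal(sym[1L, "g2"], round(am$symmetric["g1", "g2"], 2))
})
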