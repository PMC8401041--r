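# Independent oracles used across the suite; deliberately library-free and
# separate from the package's alignment/clustering code paths.

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# position-wise identity of two colinear equal-length sequences (percent)
hamming_identity <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  stopifnot(length(ca) == length(cb))
  100 * mean(ca == cb)
}

# substitute exactly k positions of a sequence with a different base
mutate_k <- function(seq, k) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  pos <- sample(seq_along(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}

# full Needleman-Wunsch with affine gaps (match +1, mismatch -1, open 4,
# extend 1); returns the optimal global score and the identity of one optimal
# alignment (matches / columns * 100)
nw_oracle <- function(a, b, match = 1, mismatch = -1, open = 4, extend = 1) {
  x <- strsplit(a, "", fixed = TRUE)[[1L]]
  y <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)   # x[i] aligned to y[j]
  Ix <- matrix(NEG, n + 1L, m + 1L)  # gap in y (x consumed)
  Iy <- matrix(NEG, n + 1L, m + 1L)  # gap in x (y consumed)
  M[1L, 1L] <- 0
  for (i in 2L:(n + 1L)) Ix[i, 1L] <- -open - extend * (i - 1L)
  for (j in 2L:(m + 1L)) Iy[1L, j] <- -open - extend * (j - 1L)
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      s <- if (x[i - 1L] == y[j - 1L]) match else mismatch
      M[i, j] <- max(M[i - 1L, j - 1L], Ix[i - 1L, j - 1L],
                     Iy[i - 1L, j - 1L]) + s
      Ix[i, j] <- max(M[i - 1L, j] - open - extend, Ix[i - 1L, j] - extend)
      Iy[i, j] <- max(M[i, j - 1L] - open - extend, Iy[i, j - 1L] - extend)
    }
  }
  score <- max(M[n + 1L, m + 1L], Ix[n + 1L, m + 1L], Iy[n + 1L, m + 1L])
  # traceback one optimal path, counting matches and columns
  i <- n + 1L; j <- m + 1L
  state <- which.max(c(M[i, j], Ix[i, j], Iy[i, j]))
  matches <- 0L; cols <- 0L
  while (i > 1L || j > 1L) {
    cols <- cols + 1L
    if (state == 1L) {
      if (x[i - 1L] == y[j - 1L]) matches <- matches + 1L
      s <- if (x[i - 1L] == y[j - 1L]) match else mismatch
      prev <- c(M[i - 1L, j - 1L], Ix[i - 1L, j - 1L], Iy[i - 1L, j - 1L])
      state <- which.max(prev)
      i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      from_m <- M[i - 1L, j] - open - extend
      from_ix <- Ix[i - 1L, j] - extend
      state <- if (from_m >= from_ix) 1L else 2L
      i <- i - 1L
    } else {
      from_m <- M[i, j - 1L] - open - extend
      from_iy <- Iy[i, j - 1L] - extend
      state <- if (from_m >= from_iy) 1L else 3L
      j <- j - 1L
    }
  }
  list(score = score, identity = 100 * matches / cols)
}

# brute-force transitive closure: ids linked whenever sim >= cutoff
closure_clusters <- function(ids, sim, cutoff) {
  labels <- seq_along(ids)
  names(labels) <- ids
  repeat {
    changed <- FALSE
    for (i in seq_along(ids)) {
      for (j in seq_along(ids)) {
        if (i != j && sim[ids[i], ids[j]] >= cutoff &&
              labels[i] != labels[j]) {
          labels[labels == labels[j]] <- labels[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(labels, unique(labels))
}

# two partitions identical up to label renaming?
same_partition <- function(a, b) {
  stopifnot(length(a) == length(b))
  identical(match(a, unique(a)), match(b, unique(b)))
}

# random additive quartet: topology ((t1,t2),(t3,t4)) with positive branch
# lengths; returns the 4x4 distance matrix and the generating lengths
random_additive_quartet <- function(taxa = c("A", "B", "C", "D")) {
  bl <- stats::runif(5L, 0.5, 5)  # a, b, c, d, internal e
  a <- bl[1L]; b <- bl[2L]; c <- bl[3L]; d <- bl[4L]; e <- bl[5L]
  D <- matrix(0, 4L, 4L, dimnames = list(taxa, taxa))
  D["A", "B"] <- D["B", "A"] <- a + b
  D["C", "D"] <- D["D", "C"] <- c + d
  D["A", "C"] <- D["C", "A"] <- a + e + c
  D["A", "D"] <- D["D", "A"] <- a + e + d
  D["B", "C"] <- D["C", "B"] <- b + e + c
  D["B", "D"] <- D["D", "B"] <- b + e + d
  list(D = D, lengths = bl)
}

# least-squares brute force over the 3 unrooted quartet topologies; returns
# the winning sister pair (as a sorted character vector) and its RSS
ls_quartet_oracle <- function(D) {
  taxa <- rownames(D)
  pairs <- utils::combn(taxa, 2L, simplify = FALSE)
  dvec <- vapply(pairs, function(p) D[p[1L], p[2L]], numeric(1L))
  topologies <- list(c("A", "B"), c("A", "C"), c("A", "D"))
  best <- NULL
  for (sis in topologies) {
    other <- setdiff(taxa, sis)
    # params: 4 tip branches + internal; path uses internal edge iff the two
    # taxa sit on opposite sides of the split
    X <- t(vapply(pairs, function(p) {
      row <- stats::setNames(numeric(5L), c(taxa, "e"))
      row[p[1L]] <- 1; row[p[2L]] <- 1
      same_side <- (all(p %in% sis)) || (all(p %in% other))
      if (!same_side) row["e"] <- 1
      row
    }, numeric(5L)))
    fit <- stats::lm.fit(X, dvec)
    rss <- sum(fit$residuals^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(sisters = sort(sis), rss = rss)
    }
  }
  best
}

# sister pair of tip1 in an unrooted 4-taxon tree
quartet_sisters <- function(tree) {
  stopifnot(length(tree$tip.label) == 4L)
  # the two tips sharing an internal node form a cherry
  for (node in unique(tree$edge[, 1L])) {
    kids <- tree$edge[tree$edge[, 1L] == node, 2L]
    tipkids <- kids[kids <= 4L]
    if (length(tipkids) == 2L) {
      cherry <- sort(tree$tip.label[tipkids])
      if ("A" %in% cherry) return(cherry)
      # the complementary cherry determines the same split
      return(sort(setdiff(tree$tip.label, cherry)))
    }
  }
  stop("no cherry found")
}
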