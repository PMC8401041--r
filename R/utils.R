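# Internal helpers shared across modules.

# Single-linkage clustering of `ids` from a pairwise similarity matrix:
# ids joined whenever similarity >= cutoff, with transitive closure.
# Delegates to stats::hclust(method = "single") on the complement distance.
# Returns an integer cluster label per id (order of first appearance).
.single_linkage <- function(ids, sim, cutoff) {
  n <- length(ids)
  if (n == 0L) return(integer(0))
  if (n == 1L) return(stats::setNames(1L, ids))
  m <- sim[ids, ids, drop = FALSE]
  if (any(is.na(m))) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop("missing similarity for pair (", ids[bad[1L]], ", ", ids[bad[2L]], ")")
  }
  d <- stats::as.dist(100 - m)
  hc <- stats::hclust(d, method = "single")
  raw <- stats::cutree(hc, h = 100 - cutoff)
  # renumber in order of first appearance over the input id order
  first <- unique(raw[ids])
  stats::setNames(match(raw[ids], first), ids)
}

# Expand a possibly sparse pair list (data.frame id_a, id_b, value) into a
# symmetric matrix with NA for unobserved pairs and 100 on the diagonal.
.pairs_to_matrix <- function(ids, pairs) {
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 100
  if (nrow(pairs)) {
    for (i in seq_len(nrow(pairs))) {
      a <- pairs$id_a[i]; b <- pairs$id_b[i]
      m[a, b] <- m[b, a] <- pairs$value[i]
    }
  }
  m
}

# Derive a reproducible child seed from a base seed and a tag; kept within
# 32-bit integer range.
.child_seed <- function(seed, tag) {
  u <- utf8ToInt(paste0(tag))
  as.integer((as.numeric(seed) * 1103515245 + sum(u * seq_along(u))) %% 2147483647)
}
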