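# Independent oracles used across the suite. These deliberately use
# different algorithms from the package implementation they check.

# Exact Steiner-minimal-tree cost in Hamming space for <= 4 binary
# terminals, by enumerating Steiner topologies and optimizing each
# coordinate independently (for a fixed topology the objective is separable
# over sites; degenerate placements cover all spanning trees and
# single-Steiner-point stars).
steiner_cost <- function(m) {
  k <- nrow(m)
  if (k == 2) return(sum(m[1, ] != m[2, ]))
  if (k == 3) {
    c1 <- colSums(m)
    return(sum(pmin(c1, 3 - c1)))
  }
  pairings <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
  best <- Inf
  for (pr in pairings) {
    a <- m[pr[1], ]; b <- m[pr[2], ]; c <- m[pr[3], ]; d <- m[pr[4], ]
    tot <- 0
    for (j in seq_along(a)) {
      costs <- vapply(0:3, function(ss) {
        s1 <- ss %% 2; s2 <- ss %/% 2
        abs(a[j] - s1) + abs(b[j] - s1) + abs(s1 - s2) +
          abs(c[j] - s2) + abs(d[j] - s2)
      }, numeric(1))
      tot <- tot + min(costs)
    }
    best <- min(best, tot)
  }
  best
}

# Enumeration of haplotype instances by site split pattern: an instance of
# k haplotypes over binary sites is determined, up to relabeling of sites
# and states (which changes no Hamming distance), by how many sites induce
# each bipartition of the haplotypes.
splits_for_k <- function(k) {
  if (k == 2) return(list(c(TRUE, FALSE)))
  if (k == 3) return(list(c(TRUE, FALSE, FALSE), c(FALSE, TRUE, FALSE),
                          c(FALSE, FALSE, TRUE)))
  list(c(TRUE, FALSE, FALSE, FALSE), c(FALSE, TRUE, FALSE, FALSE),
       c(FALSE, FALSE, TRUE, FALSE), c(FALSE, FALSE, FALSE, TRUE),
       c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE, FALSE),
       c(TRUE, FALSE, FALSE, TRUE))
}

weight_compositions <- function(total, parts) {
  if (parts == 1) return(matrix(total, 1, 1))
  out <- NULL
  for (w in 0:total)
    out <- rbind(out, cbind(w, weight_compositions(total - w, parts - 1)))
  out
}

split_instance <- function(weights, splits, k) {
  cols <- NULL
  for (i in seq_along(weights)) {
    if (weights[i] > 0)
      cols <- cbind(cols, matrix(rep(as.integer(splits[[i]]), weights[i]),
                                 k))
  }
  cols
}

# Brute-force per-bp copy counting over a small region.
brute_copy_counts <- function(blocks, chrom, max_bp) {
  counts <- integer(max_bp)
  b <- blocks[blocks$chrom == chrom, , drop = FALSE]
  for (r in seq_len(nrow(b))) {
    span <- seq(b$start[r], b$end[r] - 1)
    counts[span] <- counts[span] + 1L
  }
  counts
}

# Brute-force interval scan over sorted (pos, call) pairs on one haplotype:
# walk positions, opening a block at a TRUE after a FALSE boundary and
# closing it at the last TRUE before the next FALSE. Unknowns (NA) bridge.
brute_blocks <- function(pos, call) {
  keep <- !is.na(call)
  pos <- pos[keep]; call <- call[keep]
  out <- NULL
  open <- NA
  last_true <- NA
  for (i in seq_along(pos)) {
    if (isTRUE(call[i])) {
      if (is.na(open)) open <- pos[i]
      last_true <- pos[i]
    } else if (!is.na(open)) {
      out <- rbind(out, c(open, last_true + 1))
      open <- NA
    }
  }
  if (!is.na(open)) out <- rbind(out, c(open, last_true + 1))
  out
}

# Closed-form ordinary Procrustes fit of X onto Y (both k x 2): center,
# scale to unit centroid size, rotate by SVD with det +1.
opa_fit <- function(X, Y) {
  cs <- function(m) sweep(m, 2, colMeans(m))
  X <- cs(X); X <- X / sqrt(sum(X^2))
  Y <- cs(Y); Y <- Y / sqrt(sum(Y^2))
  s <- svd(crossprod(X, Y))
  R <- s$u %*% diag(c(1, sign(det(s$u %*% t(s$v))))) %*% t(s$v)
  X %*% R
}

# Snap true ancestry blocks to the SNP lattice convention used by
# merge_blocks: a recovered block runs from the first SNP inside the truth
# interval to the last SNP inside it, plus one.
snap_block_to_lattice <- function(start, end, spacing, chrom_len) {
  snps <- seq(spacing, chrom_len, by = spacing)
  inside <- snps[snps >= start & snps < end]
  if (!length(inside)) return(NULL)
  c(min(inside), max(inside) + 1)
}

random_founder <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}
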