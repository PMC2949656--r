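# Independent reference implementations used to cross-check the package.

# Naive O(n^3) Ward agglomeration: scan all pairs at every step, merge the
# minimum (lowest pair index on ties), update with the Lance-Williams Ward
# recurrence. Returns merge heights and the canonical partition after each
# step so tree structure can be compared without hclust's merge encoding.
bf_ward <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  members <- lapply(seq_len(n), identity)
  sizes <- rep(1, n)
  cur <- D
  heights <- numeric(n - 1)
  partitions <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    m <- nrow(cur)
    best <- c(Inf, 0L, 0L)
    for (i in seq_len(m - 1)) for (j in seq(i + 1, m))
      if (cur[i, j] < best[1]) best <- c(cur[i, j], i, j)
    i <- best[2]; j <- best[3]
    heights[step] <- best[1]
    ni <- sizes[i]; nj <- sizes[j]
    new_row <- vapply(seq_len(m), function(k) {
      if (k == i || k == j) return(NA_real_)
      nk <- sizes[k]
      ((ni + nk) * cur[i, k] + (nj + nk) * cur[j, k] - nk * cur[i, j]) /
        (ni + nj + nk)
    }, numeric(1))
    keep <- setdiff(seq_len(m), c(i, j))
    cur <- rbind(cbind(cur[keep, keep, drop = FALSE], new_row[keep]),
                 c(new_row[keep], 0))
    members <- c(members[keep], list(sort(c(members[[i]], members[[j]]))))
    sizes <- c(sizes[keep], ni + nj)
    partitions[[step]] <- canonical_partition(members)
  }
  list(heights = heights, partitions = partitions)
}

# Replay an hclust object into the same (heights, partitions) shape.
replay_hclust <- function(hc) {
  n <- length(hc$order)
  clusters <- lapply(seq_len(n), identity)   # singletons by leaf index
  merged <- vector("list", n - 1)
  partitions <- vector("list", n - 1)
  alive <- rep(TRUE, n)
  for (step in seq_len(n - 1)) {
    pick <- function(code) {
      if (code < 0) list(idx = -code, set = -code, single = TRUE)
      else list(set = merged[[code]], single = FALSE)
    }
    a <- pick(hc$merge[step, 1]); b <- pick(hc$merge[step, 2])
    merged[[step]] <- sort(c(a$set, b$set))
    current <- c(list(), merged[seq_len(step)])
    # drop merged clusters that were absorbed into later ones
    absorbed <- logical(step)
    for (s in seq_len(step)) {
      code_users <- hc$merge[seq_len(step), , drop = FALSE]
      absorbed[s] <- any(code_users == s)
    }
    singles <- setdiff(seq_len(n), unlist(merged[seq_len(step)]))
    parts <- c(lapply(singles, identity), merged[seq_len(step)][!absorbed])
    partitions[[step]] <- canonical_partition(parts)
  }
  list(heights = hc$height, partitions = partitions)
}

canonical_partition <- function(parts) {
  paste(sort(vapply(parts, function(p) paste(sort(p), collapse = ","),
                    character(1))), collapse = "|")
}

# Two-sided Fisher exact probability by full enumeration over all tables
# with the observed margins (minimum-likelihood convention).
fisher_enum <- function(tab) {
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n2):min(k, m)
  probs <- choose(m, support) * choose(n2, k - support) / choose(m + n2, k)
  p_obs <- choose(m, tab[1, 1]) * choose(n2, k - tab[1, 1]) / choose(m + n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Hypergeometric upper tail by direct summation of binomial-coefficient
# ratios (no logs).
hyper_tail_direct <- function(k, K, n, N) {
  if (k == 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Adjusted Rand index between two labelings.
ari <- function(a, b) {
  t <- table(a, b)
  n <- sum(t)
  sij <- sum(choose(t, 2))
  si <- sum(choose(rowSums(t), 2))
  sj <- sum(choose(colSums(t), 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# Does any cut of the tree isolate exactly `target` as one cluster?
isolates_group <- function(tree, target, k_max = 15L) {
  for (k in 2:min(k_max, length(tree$order))) {
    lab <- cut_dendrogram(tree, k)
    if (any(vapply(split(names(lab), lab),
                   function(m) setequal(m, target), logical(1))))
      return(TRUE)
  }
  FALSE
}

table2_path <- function() system.file("extdata", "table2_ihc.tsv",
                                      package = "apocrine")
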