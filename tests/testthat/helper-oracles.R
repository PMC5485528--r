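# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# Direct per-read product for the haploid likelihood (log10).
oracle_site_loglik <- function(bases, quals, allele) {
  e <- 10^(-quals / 10)
  p <- ifelse(bases == allele, 1 - e, e / 3)
  sum(log10(p))
}

# O(N*L) interval-stabbing depth oracle on a circular reference.
oracle_depth <- function(starts, ends, L) {
  depth <- integer(L)
  for (k in seq_along(starts)) {
    for (pos in starts[k]:ends[k]) {
      p <- ((pos - 1L) %% L) + 1L
      depth[p] <- depth[p] + 1L
    }
  }
  depth
}

# Naive column scans for complete deletion and pairwise differences.
oracle_complete_deletion_cols <- function(mat) {
  which(apply(mat, 2, function(col) all(col %in% c("A", "C", "G", "T"))))
}

oracle_pairwise_diffs <- function(mat, mode = "complete") {
  n <- nrow(mat)
  defined <- matrix(mat %in% c("A", "C", "G", "T"), nrow = n)
  d <- matrix(0L, n, n)
  if (mode == "complete") {
    keep <- oracle_complete_deletion_cols(mat)
    mat <- mat[, keep, drop = FALSE]
    defined <- defined[, keep, drop = FALSE]
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    both <- defined[i, ] & defined[j, ]
    d[i, j] <- d[j, i] <- sum(mat[i, both] != mat[j, both])
  }
  d
}

# HKY rate matrix and transition probabilities, built independently:
# matrix exponential by scaling-and-squaring of a truncated series.
oracle_hky_Q <- function(kappa, pi) {
  b <- c("A", "C", "G", "T")
  Q <- matrix(0, 4, 4, dimnames = list(b, b))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    transition <- paste0(sort(c(b[i], b[j])), collapse = "") %in% c("AG", "CT")
    Q[i, j] <- pi[j] * if (transition) kappa else 1
  }
  diag(Q) <- -rowSums(Q)
  Q / sum(-pi * diag(Q))
}

oracle_expm <- function(M) {
  k <- 12L
  A <- M / 2^k
  P <- diag(4)
  term <- diag(4)
  for (n in 1:25) {
    term <- term %*% A / n
    P <- P + term
  }
  for (i in seq_len(k)) P <- P %*% P
  P
}

# Likelihood by exhaustive summation over internal-node states.
# tree: ape phylo; works for any small tree.
oracle_hky_loglik <- function(tree, mat, kappa, pi) {
  b <- c("A", "C", "G", "T")
  Q <- oracle_hky_Q(kappa, pi)
  Pm <- lapply(tree$edge.length, function(t) oracle_expm(Q * t))
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  internal <- nt + seq_len(nn)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])
  mat <- mat[tree$tip.label, , drop = FALSE]
  total <- 0
  for (s in seq_len(ncol(mat))) {
    leaf_state <- match(mat[, s], b)
    states <- as.matrix(expand.grid(rep(list(1:4), nn)))
    site_l <- 0
    for (r in seq_len(nrow(states))) {
      st <- integer(nt + nn)
      st[seq_len(nt)] <- leaf_state
      st[internal] <- states[r, ]
      pr <- pi[st[root]]
      for (k in seq_len(nrow(tree$edge))) {
        pa <- st[tree$edge[k, 1]]; ch <- st[tree$edge[k, 2]]
        pr <- pr * Pm[[k]][pa, ch]
      }
      site_l <- site_l + pr
    }
    total <- total + log(site_l)
  }
  as.numeric(total)
}

# Small deterministic sequence helpers for fixtures.
rand_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

oracle_revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
                USE.NAMES = FALSE))
}

# Multi-alignment from named sequence strings (reference projection).
mk_msa <- function(rows) {
  cons <- lapply(names(rows), function(id)
    list(sample_id = id, tier = "relaxed", sequence = rows[[id]]))
  build_alignment(cons)
}

# Construct a pileup-column list compatible with call_site().
make_column <- function(position, bases, quals) {
  qb <- split(quals, factor(bases, levels = c("A", "C", "G", "T")))
  list(position = position, base_counts = lengths(qb),
       quals_per_base = qb, depth = length(bases))
}

# Tip-set bipartitions of an unrooted tree (each as a sorted label set,
# smaller side).
tree_bipartitions <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  all <- sort(labs)
  res <- lapply(pp, function(idx) {
    side <- sort(labs[idx])
    other <- setdiff(all, side)
    if (length(other) < length(side)) side <- sort(other)
    side
  })
  unique(res[vapply(res, function(s)
    length(s) >= 2 && length(s) <= length(all) - 2, logical(1))])
}

has_bipartition <- function(tree, tips) {
  labs <- sort(tree$tip.label)
  tips <- sort(tips)
  other <- setdiff(labs, tips)
  if (length(other) < length(tips)) tips <- sort(other)
  any(vapply(tree_bipartitions(tree), identical, logical(1), tips))
}
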