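#' HKY phylogenetic analysis parameters
#'
#' The substitution model is fixed to HKY (unequal base frequencies plus a
#' transition/transversion ratio kappa). Kappa may be supplied or left
#' NULL to be estimated by maximum likelihood alongside branch lengths;
#' base frequencies default to empirical alignment frequencies.
#'
#' @param kappa transition/transversion ratio (> 0), or NULL to estimate.
#' @param base_freqs length-4 A/C/G/T frequency vector summing to 1, or
#'   NULL for empirical frequencies.
#' @param n_bootstrap number of bootstrap pseudoreplicates (default 500).
#' @param seed RNG seed for bootstrap resampling.
#' @return object of class `phylo_params`.
#' @export
phylo_params <- function(kappa = NULL, base_freqs = NULL,
                         n_bootstrap = 500L, seed = 1L) {
  if (!is.null(kappa)) stopifnot(kappa > 0)
  if (!is.null(base_freqs))
    stopifnot(length(base_freqs) == 4, abs(sum(base_freqs) - 1) < 1e-12)
  stopifnot(n_bootstrap >= 0)
  structure(list(model = "HKY", kappa = kappa, base_freqs = base_freqs,
                 n_bootstrap = as.integer(n_bootstrap),
                 seed = as.integer(seed)),
            class = "phylo_params")
}

#' Neighbour-joining starting tree from a difference matrix
#'
#' Distances are normalised to substitutions per site
#' (`diff_counts / positions_used`) before standard Q-matrix NJ
#' agglomeration; negative intermediate branch lengths are clamped to 0.
#' The 3-taxon case uses the closed-form three-point formulas.
#'
#' @param dm a [pairwise_diffs()] or [ingest_matrix()] matrix.
#' @return an unrooted `ape::phylo` tree with branch lengths in
#'   substitutions per site.
#' @export
nj_tree <- function(dm) {
  n <- length(dm$sample_ids)
  if (n < 3L) stop("neighbour joining needs at least 3 samples")
  pu <- dm$positions_used
  if (is.matrix(pu)) {
    d <- dm$diff_counts / pu
    diag(d) <- 0
  } else {
    d <- dm$diff_counts / pu
  }
  dimnames(d) <- list(dm$sample_ids, dm$sample_ids)
  if (n == 3L) {
    v <- c(a = (d[1, 2] + d[1, 3] - d[2, 3]) / 2,
           b = (d[1, 2] + d[2, 3] - d[1, 3]) / 2,
           c = (d[1, 3] + d[2, 3] - d[1, 2]) / 2)
    tree <- list(edge = matrix(c(4L, 1L, 4L, 2L, 4L, 3L), ncol = 2,
                               byrow = TRUE),
                 edge.length = pmax(unname(v), 0),
                 tip.label = dm$sample_ids, Nnode = 1L)
    class(tree) <- "phylo"
    attr(tree, "order") <- "cladewise"
    return(tree)
  }
  tree <- ape::nj(stats::as.dist(d))
  tree$edge.length <- pmax(tree$edge.length, 0)
  ape::unroot(tree)
}

# HKY transition-probability machinery (eigendecomposition of the
# reversible rate matrix, scaled to one expected substitution per unit
# branch length).
hky_eigen <- function(kappa, pi) {
  names(pi) <- DNA_BASES
  Q <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  for (i in DNA_BASES) for (j in DNA_BASES) {
    if (i == j) next
    ti <- (i %in% c("A", "G") && j %in% c("A", "G")) ||
      (i %in% c("C", "T") && j %in% c("C", "T"))
    Q[i, j] <- pi[j] * if (ti) kappa else 1
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  sq <- sqrt(pi)
  B <- diag(sq) %*% Q %*% diag(1 / sq)
  B <- (B + t(B)) / 2
  eg <- eigen(B, symmetric = TRUE)
  list(vals = eg$values,
       left = diag(1 / sq) %*% eg$vectors,
       right = t(eg$vectors) %*% diag(sq))
}

hky_pmat <- function(eg, t) {
  eg$left %*% (exp(eg$vals * t) * eg$right)
}

compress_patterns <- function(mat) {
  key <- do.call(paste0, lapply(seq_len(nrow(mat)), function(i) mat[i, ]))
  uk <- unique(key)
  list(patterns = mat[, match(uk, key), drop = FALSE],
       weights = tabulate(match(key, uk), nbins = length(uk)))
}

empirical_base_freqs <- function(mat) {
  f <- table(factor(mat, levels = DNA_BASES))
  as.numeric(f / sum(f))
}

# Felsenstein pruning over compressed site patterns with per-node scaling.
prune_loglik <- function(tree, patt, w, eg, pi, leaf_idx) {
  tree <- stats::reorder(tree, "postorder")
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  S <- ncol(patt)
  partial <- vector("list", nn)
  logscale <- numeric(S)
  pmats <- lapply(tree$edge.length, function(t) hky_pmat(eg, t))
  for (k in seq_len(nrow(tree$edge))) {
    child <- tree$edge[k, 2]
    parent <- tree$edge[k, 1]
    if (child <= nt) {
      Lc <- matrix(0, 4, S)
      Lc[cbind(leaf_idx[child, ], seq_len(S))] <- 1
    } else {
      Lc <- partial[[child]]
    }
    contrib <- pmats[[k]] %*% Lc
    if (is.null(partial[[parent]])) partial[[parent]] <- contrib
    else partial[[parent]] <- partial[[parent]] * contrib
  }
  root <- tree$edge[nrow(tree$edge), 1]
  Lr <- partial[[root]]
  mx <- apply(Lr, 2, max)
  site_l <- as.numeric(pi %*% (Lr / rep(mx, each = 4))) * 1
  sum(w * (log(site_l) + log(mx)))
}

#' HKY log-likelihood of an alignment on a tree
#'
#' Felsenstein pruning with HKY transition probabilities from the
#' rate-matrix eigendecomposition; site patterns are compressed before
#' the tree traversal. The alignment must be gap/N-free (apply
#' [complete_deletion()] first).
#'
#' @param tree `ape::phylo` with branch lengths in substitutions/site.
#' @param msa a gap-free [build_alignment()] result.
#' @param params a [phylo_params()]; NULL kappa defaults to 2 here.
#' @return log-likelihood (natural log).
#' @export
hky_loglik <- function(tree, msa, params = phylo_params()) {
  mat <- aln_matrix(msa)
  if (any(!mat %in% DNA_BASES))
    stop("non-ACGT character in likelihood alignment; apply complete_deletion first")
  mat <- mat[tree$tip.label, , drop = FALSE]
  pi <- params$base_freqs %||% empirical_base_freqs(mat)
  kappa <- params$kappa %||% 2
  eg <- hky_eigen(kappa, pi)
  cp <- compress_patterns(mat)
  leaf_idx <- matrix(match(cp$patterns, DNA_BASES), nrow = nrow(mat))
  prune_loglik(tree, cp$patterns, cp$weights, eg, pi, leaf_idx)
}

#' Optimise branch lengths (and optionally kappa) by maximum likelihood
#'
#' Iterated bounded one-dimensional optimisation of each branch length in
#' \[0, 10\] substitutions/site, with kappa optimised on the same schedule
#' when not fixed, until the log-likelihood improves by less than `tol`
#' or `max_sweeps` sweeps. The final log-likelihood never falls below the
#' starting one.
#'
#' @param tree starting tree (typically [nj_tree()]).
#' @param msa gap-free alignment.
#' @param params a [phylo_params()]; `kappa = NULL` estimates kappa.
#' @param tol convergence tolerance on the log-likelihood.
#' @param max_sweeps maximum optimisation sweeps.
#' @return list of class `hky_fit`: `tree` (optimised branch lengths),
#'   `loglik`, `kappa`, `base_freqs`.
#' @export
optimize_branches <- function(tree, msa, params = phylo_params(),
                              tol = 1e-6, max_sweeps = 50L) {
  mat <- aln_matrix(msa)
  if (any(!mat %in% DNA_BASES))
    stop("non-ACGT character in likelihood alignment; apply complete_deletion first")
  mat <- mat[tree$tip.label, , drop = FALSE]
  pi <- params$base_freqs %||% empirical_base_freqs(mat)
  cp <- compress_patterns(mat)
  leaf_idx <- matrix(match(cp$patterns, DNA_BASES), nrow = nrow(mat))
  est_kappa <- is.null(params$kappa)
  kappa <- params$kappa %||% 2
  eg <- hky_eigen(kappa, pi)
  ll_fun <- function(tr, egl) prune_loglik(tr, cp$patterns, cp$weights,
                                           egl, pi, leaf_idx)
  cur <- ll_fun(tree, eg)
  start_ll <- cur
  for (sweep in seq_len(max_sweeps)) {
    prev <- cur
    for (k in seq_along(tree$edge.length)) {
      f <- function(t) {
        tr <- tree; tr$edge.length[k] <- t
        -ll_fun(tr, eg)
      }
      op <- optimize(f, interval = c(0, 10), tol = 1e-8)
      if (-op$objective > cur) {
        tree$edge.length[k] <- op$minimum
        cur <- -op$objective
      }
    }
    if (est_kappa) {
      fk <- function(lk) {
        -ll_fun(tree, hky_eigen(exp(lk), pi))
      }
      opk <- optimize(fk, interval = log(c(0.05, 100)), tol = 1e-6)
      if (-opk$objective > cur) {
        kappa <- exp(opk$minimum)
        eg <- hky_eigen(kappa, pi)
        cur <- -opk$objective
      }
    }
    if (cur - prev < tol) break
  }
  stopifnot(cur >= start_ll - 1e-9)
  structure(list(tree = tree, loglik = cur, kappa = kappa,
                 base_freqs = pi),
            class = "hky_fit")
}

msa_pdist <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    d[i, j] <- d[j, i] <- mean(mat[i, ] != mat[j, ])
  }
  d
}

nj_from_pdist <- function(d) {
  dmobj <- list(sample_ids = rownames(d), diff_counts = d,
                positions_used = 1, deletion_mode = "complete")
  nj_tree(dmobj)
}

#' Nonparametric bootstrap support for the ML tree
#'
#' Builds the reference tree (NJ start on alignment p-distances, HKY
#' branch-length optimisation), then resamples alignment columns with
#' replacement `n_bootstrap` times, rebuilds an NJ tree per replicate, and
#' reports for each internal edge of the reference tree the percentage of
#' replicates containing that bipartition. Because no topology search
#' beyond the NJ start is performed, per-replicate branch-length
#' optimisation cannot change any bipartition and is off by default.
#'
#' @param msa gap-free alignment.
#' @param params a [phylo_params()] (uses `n_bootstrap`, `seed`).
#' @param optimize_replicates also optimise branch lengths within each
#'   replicate (slower; identical supports).
#' @return list of class `bootstrap_phylo`: `fit` (the reference
#'   [optimize_branches()] fit), `tree` (reference tree with node labels
#'   set to support percentages), `support` (per internal node, percent),
#'   `n_bootstrap`.
#' @export
bootstrap_support <- function(msa, params = phylo_params(),
                              optimize_replicates = FALSE) {
  stopifnot(params$n_bootstrap >= 1)
  mat <- aln_matrix(msa)
  d <- msa_pdist(mat)
  start <- nj_from_pdist(d)
  fit <- optimize_branches(start, msa, params)
  set.seed(params$seed)
  S <- ncol(mat)
  boots <- vector("list", params$n_bootstrap)
  for (b in seq_len(params$n_bootstrap)) {
    cols <- sample.int(S, S, replace = TRUE)
    bm <- mat[, cols, drop = FALSE]
    bt <- nj_from_pdist(msa_pdist(bm))
    if (optimize_replicates) {
      bmsa <- structure(list(sample_ids = rownames(bm),
                             rows = apply(bm, 1, paste, collapse = ""),
                             n_columns = ncol(bm), source = "bootstrap"),
                        class = "multi_alignment")
      bt <- optimize_branches(bt, bmsa, params)$tree
    }
    boots[[b]] <- bt
  }
  class(boots) <- "multiPhylo"
  cnt <- ape::prop.clades(fit$tree, boots, rooted = FALSE)
  cnt[is.na(cnt)] <- 0
  support <- 100 * cnt / params$n_bootstrap
  tree <- fit$tree
  tree$node.label <- formatC(support, format = "f", digits = 0)
  structure(list(fit = fit, tree = tree, support = support,
                 n_bootstrap = params$n_bootstrap),
            class = "bootstrap_phylo")
}

#' Write a tree with support labels as newick
#' @param x an `ape::phylo` or [bootstrap_support()] result.
#' @param path output newick path.
#' @export
write_tree <- function(x, path) {
  tree <- if (inherits(x, "bootstrap_phylo")) x$tree
  else if (inherits(x, "hky_fit")) x$tree else x
  ape::write.tree(tree, file = path)
  invisible(path)
}
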