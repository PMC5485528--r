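#' Assemble a multi-sample alignment
#'
#' Default mode is reference projection: because every consensus lives in
#' shared reference coordinates, the rows are simply the consensus strings
#' and no multiple-alignment heuristic is needed for substitution-only
#' mitogenomes. An externally produced alignment FASTA (e.g. from Muscle)
#' can be ingested instead; rows must be equal length in either mode.
#'
#' @param consensuses list of [apply_tier()] consensuses
#'   (reference_projection mode), or a path to an alignment FASTA
#'   (external mode).
#' @param mode "reference_projection" or "external".
#' @return object of class `multi_alignment`: `sample_ids`, `rows` (named
#'   character vector over A/C/G/T/N/-), `n_columns`, `source`.
#' @export
build_alignment <- function(consensuses,
                            mode = c("reference_projection", "external")) {
  mode <- match.arg(mode)
  if (mode == "reference_projection") {
    rows <- vapply(consensuses, `[[`, character(1), "sequence")
    ids <- vapply(consensuses, `[[`, character(1), "sample_id")
  } else {
    ss <- Biostrings::readBStringSet(consensuses)
    rows <- toupper(as.character(ss))
    ids <- sub("\\s.*$", "", names(ss))
  }
  if (anyDuplicated(ids)) stop("duplicate sample ids in alignment")
  if (length(unique(nchar(rows))) > 1L)
    stop("alignment rows have unequal lengths: ",
         paste(nchar(rows), collapse = ", "))
  names(rows) <- ids
  structure(list(sample_ids = ids, rows = rows,
                 n_columns = unname(nchar(rows[1])), source = mode),
            class = "multi_alignment")
}

#' @export
print.multi_alignment <- function(x, ...) {
  cat(sprintf("<multi_alignment> %d samples x %d columns (%s)\n",
              length(x$sample_ids), x$n_columns, x$source))
  invisible(x)
}

aln_matrix <- function(msa) {
  m <- do.call(rbind, strsplit(unname(msa$rows), ""))
  rownames(m) <- msa$sample_ids
  m
}

#' Remove columns with gaps or missing data in any sample
#'
#' Complete deletion: only columns where every row carries an A/C/G/T base
#' survive; gap characters '-' are treated exactly like N. Column order is
#' preserved and the operation is idempotent.
#'
#' @param msa a [build_alignment()] result.
#' @return a `multi_alignment` restricted to the surviving columns, with
#'   `kept_columns` recording their original indices.
#' @export
complete_deletion <- function(msa) {
  m <- aln_matrix(msa)
  keep <- colSums(matrix(m %in% DNA_BASES, nrow = nrow(m))) == nrow(m)
  rows <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  if (sum(keep) == 0L) rows <- setNames(rep("", nrow(m)), msa$sample_ids)
  structure(list(sample_ids = msa$sample_ids, rows = rows,
                 n_columns = sum(keep), source = msa$source,
                 kept_columns = which(keep)),
            class = "multi_alignment")
}

#' Pairwise base-difference matrix
#'
#' Counts, for every sample pair, the alignment columns at which both
#' carry a defined base and the bases differ (count-form p-distance).
#' Complete mode first applies [complete_deletion()] (enforced
#' internally), so every pair is compared over the same column set;
#' pairwise mode drops undefined columns per pair.
#'
#' @param msa a [build_alignment()] result.
#' @param mode "complete" or "pairwise" deletion.
#' @return object of class `distance_matrix`: `sample_ids`, `diff_counts`
#'   (symmetric integer matrix, zero diagonal), `positions_used` (scalar
#'   in complete mode, per-pair matrix in pairwise mode), `deletion_mode`.
#' @export
pairwise_diffs <- function(msa, mode = c("complete", "pairwise")) {
  mode <- match.arg(mode)
  if (mode == "complete") msa <- complete_deletion(msa)
  m <- aln_matrix(msa)
  n <- nrow(m)
  defined <- matrix(m %in% DNA_BASES, nrow = n)
  d <- matrix(0L, n, n, dimnames = list(msa$sample_ids, msa$sample_ids))
  pu <- matrix(ncol(m), n, n, dimnames = dimnames(d))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    both <- defined[i, ] & defined[j, ]
    d[i, j] <- d[j, i] <- sum(m[i, both] != m[j, both])
    pu[i, j] <- pu[j, i] <- sum(both)
  }
  structure(list(sample_ids = msa$sample_ids, diff_counts = d,
                 positions_used = if (mode == "complete") ncol(m) else pu,
                 deletion_mode = mode),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> %d samples, %s deletion, positions used: %s\n",
              length(x$sample_ids), x$deletion_mode,
              if (is.matrix(x$positions_used)) "per pair"
              else x$positions_used))
  print(x$diff_counts)
  invisible(x)
}

pair_positions_used <- function(dm, i, j) {
  if (is.matrix(dm$positions_used)) dm$positions_used[i, j]
  else dm$positions_used
}

#' Report zero-distance identity matches
#'
#' Two museum samples are called a match when their consensus mitogenomes
#' are identical over the compared columns (difference count 0) and the
#' comparison rests on at least `min_overlap` positions -- the guard keeps
#' a near-empty shared column set from producing a vacuous "identical"
#' call.
#'
#' @param dm a [pairwise_diffs()] matrix.
#' @param min_overlap minimum positions used for a pair to be matchable.
#' @return object of class `match_report`: `pairs` (every pair with its
#'   difference count and positions used, sorted ascending by count) and
#'   `matched` (the zero-difference subset meeting `min_overlap`).
#' @export
match_candidates <- function(dm, min_overlap = 10000L) {
  ids <- dm$sample_ids
  n <- length(ids)
  rows <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    rows[[length(rows) + 1L]] <- data.frame(
      sample_a = ids[i], sample_b = ids[j],
      diff_count = dm$diff_counts[i, j],
      positions_used = pair_positions_used(dm, i, j),
      stringsAsFactors = FALSE)
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_a = character(0), sample_b = character(0),
               diff_count = integer(0), positions_used = integer(0),
               stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$diff_count, pairs$sample_a, pairs$sample_b), ]
  rownames(pairs) <- NULL
  matched <- pairs[pairs$diff_count == 0 &
                     pairs$positions_used >= min_overlap, , drop = FALSE]
  rownames(matched) <- NULL
  structure(list(pairs = pairs, matched = matched,
                 min_overlap = min_overlap),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  if (nrow(x$matched) == 0L) {
    cat("<match_report> no identical pairs\n")
  } else {
    cat("<match_report> identical pairs:\n")
    for (k in seq_len(nrow(x$matched)))
      cat(sprintf("  %s == %s over %d positions\n",
                  x$matched$sample_a[k], x$matched$sample_b[k],
                  x$matched$positions_used[k]))
  }
  invisible(x)
}

#' Write a distance matrix as TSV (square form)
#' @param dm a [pairwise_diffs()] matrix.
#' @param path output TSV.
#' @export
write_distance_matrix <- function(dm, path) {
  df <- as.data.frame(dm$diff_counts)
  df <- cbind(sample = rownames(dm$diff_counts), df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Ingest a pairwise difference matrix from TSV
#'
#' Accepts a square numeric matrix with header labels and a label column,
#' or a lower-triangular layout (empty upper cells); symmetry is enforced
#' and validated. This is the worked-example entry point for published
#' pairwise-difference tables.
#'
#' @param path TSV file.
#' @return a `distance_matrix` (positions_used NA until known; pass it to
#'   [match_candidates()] with `min_overlap` covered via
#'   `positions_used` argument).
#' @param positions_used number of alignment positions behind the counts.
#' @export
ingest_matrix <- function(path, positions_used = NA_integer_) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   row.names = 1, stringsAsFactors = FALSE,
                   fill = TRUE, na.strings = c("", "NA"))
  m <- as.matrix(df)
  mode(m) <- "numeric"
  if (nrow(m) != ncol(m))
    stop("matrix must be square (got ", nrow(m), " x ", ncol(m), ")")
  ids <- rownames(m)
  lower <- m; lower[upper.tri(lower)] <- NA
  filled <- lower
  filled[upper.tri(filled)] <- t(lower)[upper.tri(lower)]
  dg <- diag(filled)
  dg[is.na(dg)] <- 0
  diag(filled) <- dg
  full_given <- !anyNA(m)
  if (full_given && any(m != t(m)))
    stop("asymmetric full matrix")
  if (anyNA(filled))
    stop("matrix has missing off-diagonal entries")
  if (any(filled < 0)) stop("negative difference counts")
  if (any(diag(filled) != 0)) stop("nonzero diagonal")
  storage.mode(filled) <- "integer"
  dimnames(filled) <- list(ids, ids)
  structure(list(sample_ids = ids, diff_counts = filled,
                 positions_used = positions_used,
                 deletion_mode = "complete"),
            class = "distance_matrix")
}
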