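#' Consensus filter tiers
#'
#' The two shipped presets carry the study's thresholds. Relaxed: GQ >= 30,
#' depth >= 3, majority-allele frequency strictly above 33%, and a sample
#' enters the final alignment if at most 33% of its sites are missing.
#' Strict: GQ >= 30, depth >= 10, majority frequency strictly above 90%,
#' at most 20% missing. "No more than X% missing" is inclusive; "GQ less
#' than 30 filtered" means GQ 30 passes; the allele-frequency rule is a
#' strict inequality.
#'
#' @param name "relaxed" or "strict".
#' @return object of class `filter_tier` with fields `name`, `min_gq`,
#'   `min_depth`, `min_allele_fraction`, `max_missing_fraction`.
#' @export
filter_tier <- function(name = c("relaxed", "strict")) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("relaxed", "strict"))
    stop("unknown filter tier: ", paste(name, collapse = ", "))
  if (name == "relaxed") {
    structure(list(name = "relaxed", min_gq = 30L, min_depth = 3L,
                   min_allele_fraction = 0.33,
                   max_missing_fraction = 0.33),
              class = "filter_tier")
  } else {
    structure(list(name = "strict", min_gq = 30L, min_depth = 10L,
                   min_allele_fraction = 0.90,
                   max_missing_fraction = 0.20),
              class = "filter_tier")
  }
}

#' Build a consensus sequence under a filter tier
#'
#' A site emits its called allele iff GQ >= `min_gq`, depth >= `min_depth`
#' and the best allele's read fraction is strictly greater than
#' `min_allele_fraction`; every other site (including no-calls) becomes N.
#' Missingness is accounted against the full reference length, matching
#' the per-sample sequence-length bookkeeping of the study design.
#'
#' @param calls a [call_sites()] data.frame (one row per reference
#'   position).
#' @param tier a [filter_tier()].
#' @param sample_id sample name for the output record.
#' @return object of class `consensus_seq`: `sample_id`, `tier`,
#'   `sequence` (A/C/G/T/N, reference length), `defined_count`,
#'   `missing_fraction`, `fail_reason` (per-site first failing rule, for
#'   the filter audit).
#' @export
apply_tier <- function(calls, tier, sample_id = "sample") {
  stopifnot(inherits(tier, "filter_tier"))
  n <- nrow(calls)
  nocall <- is.na(calls$best_allele)
  ok_gq <- !nocall & !is.na(calls$gq) & calls$gq >= tier$min_gq
  ok_dp <- !nocall & calls$depth >= tier$min_depth
  ok_af <- !nocall & !is.na(calls$allele_fraction) &
    calls$allele_fraction > tier$min_allele_fraction
  # exact count ties between the called base and another allele are
  # masked rather than risk an arbitrary call
  af2 <- calls$allele_fraction2
  if (!is.null(af2))
    ok_af <- ok_af & (is.na(af2) | calls$allele_fraction != af2)
  pass <- ok_gq & ok_dp & ok_af
  seq <- ifelse(pass, calls$best_allele, "N")
  fail <- rep("pass", n)
  fail[!ok_af] <- "allele_fraction"
  fail[!ok_dp] <- "depth"
  fail[!ok_gq] <- "gq"
  fail[nocall] <- "no_call"
  defined <- sum(pass)
  structure(list(sample_id = sample_id, tier = tier$name,
                 sequence = paste(seq, collapse = ""),
                 defined_count = defined,
                 missing_fraction = 1 - defined / n,
                 fail_reason = fail),
            class = "consensus_seq")
}

#' @export
print.consensus_seq <- function(x, ...) {
  cat(sprintf("<consensus_seq> %s [%s]: %d/%d defined (%.1f%% missing)\n",
              x$sample_id, x$tier, x$defined_count,
              nchar(x$sequence), 100 * x$missing_fraction))
  invisible(x)
}

#' Decide whether a sample enters the final alignment
#'
#' A sample is included iff its consensus missing fraction is at most the
#' tier's `max_missing_fraction` (inclusive boundary).
#'
#' @param cs a [apply_tier()] consensus.
#' @param tier a [filter_tier()].
#' @return list with `included` (logical) and `reason` (text reporting
#'   both the observed and the allowed missing fraction).
#' @export
include_sample <- function(cs, tier) {
  stopifnot(inherits(cs, "consensus_seq"), inherits(tier, "filter_tier"))
  inc <- cs$missing_fraction <= tier$max_missing_fraction
  list(included = inc,
       reason = sprintf("%s [%s]: missing %.4f vs allowed %.2f -> %s",
                        cs$sample_id, tier$name, cs$missing_fraction,
                        tier$max_missing_fraction,
                        if (inc) "included" else "excluded"))
}

#' Write consensus sequences to FASTA
#' @param consensuses list of [apply_tier()] results.
#' @param path output FASTA.
#' @export
write_consensus_fasta <- function(consensuses, path) {
  seqs <- vapply(consensuses, `[[`, character(1), "sequence")
  names(seqs) <- vapply(consensuses, function(x)
    paste0(x$sample_id, "_", x$tier), character(1))
  write_fasta(seqs, path)
}

#' Write the per-site filter audit as TSV
#' @param cs a [apply_tier()] consensus.
#' @param path output TSV.
#' @export
write_filter_audit <- function(cs, path) {
  df <- data.frame(position = seq_along(cs$fail_reason),
                   result = cs$fail_reason)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
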