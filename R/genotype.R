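#' Call a haploid genotype at one pileup column
#'
#' Per-allele log10-likelihoods follow the standard haploid model: a read
#' whose base matches the candidate allele contributes `log10(1 - e)`, any
#' other read contributes `log10(e / 3)`, with `e` the (rescaled) Phred
#' error probability. The best allele is the argmax; exact likelihood ties
#' go to the reference base when it is among the tied set, otherwise to the
#' alphabetically first allele, with GQ 0. GQ is the Phred-scaled log10
#' ratio of best to second-best likelihood, capped at 99.
#'
#' @param col a [pileup_column()] (needs `quals_per_base`, `depth`).
#' @param ref_base reference base at the column.
#' @return list of class `haploid_call`: `position`, `ref_base`,
#'   `best_allele`, `depth`, `allele_fraction`, `gq`, `per_allele_loglik`
#'   (log10, named A/C/G/T). Depth-0 columns give a no-call (`best_allele`
#'   NA).
#' @export
call_site <- function(col, ref_base) {
  quals <- col$quals_per_base
  depth <- sum(lengths(quals))
  if (depth == 0L) {
    return(structure(list(position = col$position, ref_base = ref_base,
                          best_allele = NA_character_, depth = 0L,
                          allele_fraction = NA_real_, gq = NA_integer_,
                          per_allele_loglik = setNames(rep(NA_real_, 4),
                                                       DNA_BASES)),
                     class = "haploid_call"))
  }
  ll <- setNames(numeric(4), DNA_BASES)
  for (b in DNA_BASES) {
    acc <- 0
    for (ob in DNA_BASES) {
      q <- quals[[ob]]
      if (!length(q)) next
      e <- phred_to_err(q)
      acc <- acc + if (ob == b) sum(log10(1 - e)) else sum(log10(e / 3))
    }
    ll[b] <- acc
  }
  mx <- max(ll)
  tied <- DNA_BASES[ll == mx]
  best <- if (length(tied) > 1L) {
    if (ref_base %in% tied) ref_base else tied[1]
  } else tied
  second <- max(ll[DNA_BASES != best])
  gq <- if (length(tied) > 1L) 0L else
    min(99L, as.integer(round(10 * (mx - second))))
  counts <- lengths(quals)
  structure(list(position = col$position, ref_base = ref_base,
                 best_allele = best, depth = as.integer(depth),
                 allele_fraction = unname(counts[best] / depth),
                 allele_fraction2 = unname(max(counts[DNA_BASES != best]) /
                                             depth),
                 gq = gq, per_allele_loglik = ll),
            class = "haploid_call")
}

#' Call haploid genotypes at every reference position
#'
#' Vectorised all-sites caller over a pileup; per-site semantics are
#' identical to [call_site()] (the test suite checks the two paths against
#' each other and against a brute-force likelihood oracle). All-sites
#' output (including depth-0 no-calls) is kept because the consensus stage
#' needs per-site evidence genome-wide.
#'
#' @param p a [pileup()] object.
#' @param ref a [mito_reference()].
#' @return data.frame of class `haploid_calls`, one row per reference
#'   position: `position`, `ref_base`, `best_allele`, `depth`,
#'   `allele_fraction`, `gq`, `ll_A`..`ll_T` (log10).
#' @export
call_sites <- function(p, ref) {
  L <- p$ref_length
  stopifnot(L == length(ref))
  refch <- strsplit(ref$sequence, "")[[1]]
  out <- data.frame(position = seq_len(L), ref_base = refch,
                    best_allele = NA_character_, depth = p$depth,
                    allele_fraction = NA_real_, allele_fraction2 = NA_real_,
                    gq = NA_integer_,
                    ll_A = NA_real_, ll_C = NA_real_, ll_G = NA_real_,
                    ll_T = NA_real_, stringsAsFactors = FALSE)
  eb <- p$bases
  if (!length(eb$pos)) return(structure(out, class = c("haploid_calls", "data.frame")))
  cov_pos <- sort(unique(eb$pos))
  f <- match(eb$pos, cov_pos)
  e <- phred_to_err(eb$qual)
  wmis <- log10(e / 3)
  delta <- log10(1 - e) - wmis
  C <- rowsum(wmis, f)[, 1]
  S <- matrix(0, nrow = length(cov_pos), ncol = 4,
              dimnames = list(NULL, DNA_BASES))
  for (b in DNA_BASES) {
    sel <- eb$base == b
    if (any(sel)) {
      rs <- rowsum(delta[sel], f[sel])
      S[as.integer(rownames(rs)), b] <- rs[, 1]
    }
  }
  ll <- C + S
  mx <- do.call(pmax, as.data.frame(ll))
  tie_mat <- ll == mx
  n_tied <- rowSums(tie_mat)
  ref_idx <- match(refch[cov_pos], DNA_BASES)
  first_tied <- max.col(tie_mat, ties.method = "first")
  ref_is_tied <- tie_mat[cbind(seq_along(cov_pos), ref_idx)]
  best_idx <- ifelse(n_tied > 1L & ref_is_tied, ref_idx, first_tied)
  ll2 <- ll
  ll2[cbind(seq_along(cov_pos), best_idx)] <- -Inf
  second <- do.call(pmax, as.data.frame(ll2))
  gq <- ifelse(n_tied > 1L, 0L,
               pmin(99L, as.integer(round(10 * (mx - second)))))
  counts <- p$counts[cov_pos, , drop = FALSE]
  best <- DNA_BASES[best_idx]
  out$best_allele[cov_pos] <- best
  out$allele_fraction[cov_pos] <-
    counts[cbind(seq_along(cov_pos), best_idx)] / p$depth[cov_pos]
  cnt2 <- counts
  cnt2[cbind(seq_along(cov_pos), best_idx)] <- -1L
  out$allele_fraction2[cov_pos] <-
    do.call(pmax, as.data.frame(cnt2)) / p$depth[cov_pos]
  out$gq[cov_pos] <- gq
  out$ll_A[cov_pos] <- ll[, "A"]; out$ll_C[cov_pos] <- ll[, "C"]
  out$ll_G[cov_pos] <- ll[, "G"]; out$ll_T[cov_pos] <- ll[, "T"]
  structure(out, class = c("haploid_calls", "data.frame"))
}

#' Write haploid calls as VCF 4.2
#'
#' All-sites, single-sample, haploid VCF: POS is 1-based, GT is 0/1
#' against the best allele (or "." at no-call sites), with DP, GQ and AD
#' carried in the sample column. The file round-trips through
#' [read_vcf()] for every field the pipeline consumes.
#'
#' @param calls a [call_sites()] data.frame sorted by position.
#' @param ref a [mito_reference()].
#' @param sample_id sample column name.
#' @param path output path.
#' @export
write_vcf <- function(calls, ref, sample_id, path) {
  if (is.unsorted(calls$position))
    stop("calls must be sorted by position")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", ref$id, length(ref)),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Site depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample_id)), con)
  nocall <- is.na(calls$best_allele)
  is_var <- !nocall & calls$best_allele != calls$ref_base
  alt <- ifelse(is_var, calls$best_allele, ".")
  gt <- ifelse(nocall, ".", ifelse(is_var, "1", "0"))
  gq <- ifelse(nocall, ".", as.character(calls$gq))
  dp <- as.character(calls$depth)
  ad_ref <- round(ifelse(nocall, 0,
                         ifelse(is_var,
                                calls$depth * (1 - calls$allele_fraction),
                                calls$depth * calls$allele_fraction)))
  ad <- ifelse(is_var,
               paste0(ad_ref, ",",
                      round(calls$depth * calls$allele_fraction)),
               as.character(ad_ref))
  writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tDP=%s\tGT:DP:GQ:AD\t%s:%s:%s:%s",
                     ref$id, calls$position, calls$ref_base, alt, dp,
                     gt, dp, gq, ad), con)
  invisible(path)
}

#' Read a pipeline VCF back into a calls table
#'
#' Uses vcfR when installed, otherwise a minimal reader for the
#' single-sample haploid layout written by [write_vcf()]. Only the fields
#' the pipeline consumes (position, ref/best allele, depth, GQ,
#' allele fraction) are reconstructed.
#'
#' @param path VCF file.
#' @return data.frame of class `haploid_calls` (likelihood columns NA).
#' @export
read_vcf <- function(path) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- v@fix
    gt <- vcfR::extract.gt(v, "GT")[, 1]
    gq <- suppressWarnings(as.integer(vcfR::extract.gt(v, "GQ")[, 1]))
    dp <- as.integer(vcfR::extract.gt(v, "DP")[, 1])
    ad <- vcfR::extract.gt(v, "AD")[, 1]
    pos <- as.integer(fix[, "POS"])
    refb <- fix[, "REF"]
    altb <- fix[, "ALT"]
  } else {
    ln <- readLines(path)
    ln <- ln[!startsWith(ln, "#")]
    f <- strsplit(ln, "\t")
    pos <- vapply(f, function(x) as.integer(x[2]), integer(1))
    refb <- vapply(f, `[[`, character(1), 4)
    altb <- vapply(f, `[[`, character(1), 5)
    smp <- strsplit(vapply(f, `[[`, character(1), 10), ":")
    gt <- vapply(smp, `[[`, character(1), 1)
    dp <- vapply(smp, function(x) as.integer(x[2]), integer(1))
    gq <- suppressWarnings(vapply(smp, function(x) as.integer(x[3]),
                                  integer(1)))
    ad <- vapply(smp, `[[`, character(1), 4)
  }
  nocall <- gt == "." | is.na(gt)
  best <- ifelse(nocall, NA_character_, ifelse(gt == "1", altb, refb))
  ad_best <- vapply(strsplit(ad, ","), function(x) {
    as.numeric(x[length(x)])
  }, numeric(1))
  af <- ifelse(nocall | dp == 0, NA_real_, ad_best / dp)
  out <- data.frame(position = pos, ref_base = refb, best_allele = best,
                    depth = dp, allele_fraction = af,
                    allele_fraction2 = NA_real_,
                    gq = ifelse(nocall, NA_integer_, gq),
                    ll_A = NA_real_, ll_C = NA_real_, ll_G = NA_real_,
                    ll_T = NA_real_, stringsAsFactors = FALSE)
  out <- out[order(out$position), ]
  rownames(out) <- NULL
  structure(out, class = c("haploid_calls", "data.frame"))
}
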