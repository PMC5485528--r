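#' Estimate terminal deamination profiles from alignments
#'
#' Measures, at each terminal offset `i` (0-based, counted 5'->3' in read
#' orientation), the frequency of deamination-consistent mismatches
#' against the reference: `ct5[i]` is the fraction of read bases at 5'
#' offset `i` that read T where the reference has C; `ga3` is the G->A
#' analogue from the 3' end and `ct3` the 3' C->T series (the informative
#' one for single-stranded libraries, which are deaminated at both ends).
#' A geometric decay `d_i = d0 * lam^i` is fitted to the 5' C->T series by
#' least squares over offsets with at least `min_informative` reference-C
#' observations.
#'
#' @param alns aligned reads (reference-orientation `seq`/`qual`).
#' @param ref a [mito_reference()].
#' @param window number of terminal offsets profiled.
#' @param library_type library protocol; controls which ends are rescaled
#'   later.
#' @param min_informative minimum informative observations for an offset
#'   to enter the fit.
#' @return object of class `damage_profile`: `ct5`, `ct3`, `ga3`,
#'   `n_ct5` (informative counts), `fitted_d0`, `fitted_lam`, `window`,
#'   `library_type`, `flagged`.
#' @export
estimate_damage <- function(alns, ref, window = 25L,
                            library_type = c("single_stranded",
                                             "double_stranded"),
                            min_informative = 25L) {
  library_type <- match.arg(library_type)
  if (nrow(alns) == 0L) stop("estimate_damage needs at least one alignment")
  L <- length(ref)
  eb <- expand_bases(alns, L)
  refch <- strsplit(ref$sequence, "")[[1]][eb$pos]
  neg <- eb$strand == "-"
  # read-orientation base, reference base and terminal offsets
  rbase <- ifelse(neg, chartr("ACGT", "TGCA", eb$base), eb$base)
  rref  <- ifelse(neg, chartr("ACGT", "TGCA", refch), refch)
  o5 <- ifelse(neg, eb$off3, eb$off5)
  o3 <- ifelse(neg, eb$off5, eb$off3)

  freq_at <- function(off, from, to) {
    sel <- off < window & rref == from
    denom <- tabulate(off[sel] + 1L, nbins = window)
    num <- tabulate(off[sel & rbase == to] + 1L, nbins = window)
    list(freq = ifelse(denom > 0, num / denom, NA_real_), n = denom)
  }
  f5 <- freq_at(o5, "C", "T")
  f3c <- freq_at(o3, "C", "T")
  f3g <- freq_at(o3, "G", "A")

  usable <- which(f5$n >= min_informative)
  flagged <- length(usable) == 0L
  if (!flagged) {
    obs <- f5$freq[usable]
    offs <- usable - 1L
    ssq <- function(p) sum((p[1] * p[2]^offs - obs)^2)
    d0_init <- max(obs[1], 1e-4)
    lam_init <- if (length(obs) > 1 && obs[1] > 0 && obs[2] > 0)
      min(max(obs[2] / obs[1], 0.05), 0.95) else 0.5
    fit <- optim(c(d0_init, lam_init), ssq, method = "L-BFGS-B",
                 lower = c(0, 1e-6), upper = c(1, 0.9999))
    d0 <- fit$par[1]; lam <- fit$par[2]
  } else {
    d0 <- NA_real_; lam <- NA_real_
  }
  structure(list(ct5 = f5$freq, ct3 = f3c$freq, ga3 = f3g$freq,
                 n_ct5 = f5$n, fitted_d0 = d0, fitted_lam = lam,
                 window = as.integer(window), library_type = library_type,
                 flagged = flagged),
            class = "damage_profile")
}

#' @export
print.damage_profile <- function(x, ...) {
  cat(sprintf("<damage_profile> %s: d0 = %.4f, lam = %.4f, window = %d%s\n",
              x$library_type, x$fitted_d0, x$fitted_lam, x$window,
              if (x$flagged) " [fit undefined]" else ""))
  invisible(x)
}

#' Write a damage profile as TSV (per-offset series) plus JSON fit
#' @param profile a [estimate_damage()] result.
#' @param tsv_path,json_path output paths (NULL to skip either).
#' @export
write_damage_profile <- function(profile, tsv_path, json_path = NULL) {
  df <- data.frame(offset = seq_len(profile$window) - 1L,
                   ct5 = profile$ct5, ct3 = profile$ct3, ga3 = profile$ga3,
                   n_ct5 = profile$n_ct5)
  write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(fitted_d0 = profile$fitted_d0,
                              fitted_lam = profile$fitted_lam,
                              window = profile$window,
                              library_type = profile$library_type,
                              flagged = profile$flagged),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(tsv_path)
}

#' Rescale base qualities of damage-consistent mismatches
#'
#' For every read base whose mismatch against the reference is consistent
#' with deamination chemistry (read-orientation T over reference C at a
#' terminal offset; plus the 3' G-over-A analogue for double-stranded
#' libraries, or C->T at both ends for single-stranded libraries), the
#' Phred error probability is inflated to `e' = e + d_i * (1 - e)` with
#' `d_i = fitted_d0 * fitted_lam^i` (zero at offsets beyond the profile
#' window), and the quality becomes `round(-10 * log10(e'))`. When a base
#' sits within reach of both ends the per-end damage probabilities are
#' combined as `1 - (1-d5)(1-d3)`. All other bases are unchanged;
#' rescaling never increases a quality.
#'
#' @param alns aligned reads.
#' @param profile a fitted [estimate_damage()] profile.
#' @param ref a [mito_reference()].
#' @return alignments with rescaled `qual` strings.
#' @export
rescale_quals <- function(alns, profile, ref) {
  stopifnot(inherits(profile, "damage_profile"))
  if (profile$flagged || is.na(profile$fitted_d0))
    stop("damage profile fit is undefined; cannot rescale")
  if (nrow(alns) == 0L || profile$fitted_d0 == 0) return(alns)
  L <- length(ref)
  eb <- expand_bases(alns, L)
  refch <- strsplit(ref$sequence, "")[[1]][eb$pos]
  neg <- eb$strand == "-"
  rbase <- ifelse(neg, chartr("ACGT", "TGCA", eb$base), eb$base)
  rref  <- ifelse(neg, chartr("ACGT", "TGCA", refch), refch)
  o5 <- ifelse(neg, eb$off3, eb$off5)
  o3 <- ifelse(neg, eb$off5, eb$off3)
  dmg_at <- function(off) {
    d <- profile$fitted_d0 * profile$fitted_lam^off
    d[off >= profile$window] <- 0
    d
  }
  d5 <- dmg_at(o5); d3 <- dmg_at(o3)
  ct <- rbase == "T" & rref == "C"
  if (profile$library_type == "single_stranded") {
    d <- ifelse(ct, 1 - (1 - d5) * (1 - d3), 0)
  } else {
    ga <- rbase == "A" & rref == "G"
    d <- ifelse(ct, d5, 0) + ifelse(ga, d3, 0)
  }
  hit <- d > 0
  if (any(hit)) {
    e <- phred_to_err(eb$qual[hit])
    e2 <- e + d[hit] * (1 - e)
    eb$qual[hit] <- pmax(err_to_phred(e2), 0L)
  }
  qr <- as.raw(pmin(eb$qual, 93L) + 33L)
  lens <- alns$end - alns$start + 1L
  ends <- cumsum(lens); starts <- ends - lens + 1L
  alns$qual <- vapply(seq_len(nrow(alns)),
                      function(i) rawToChar(qr[starts[i]:ends[i]]),
                      character(1))
  alns
}
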