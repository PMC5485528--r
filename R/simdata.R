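#' Deamination damage parameters
#'
#' Terminal cytosine deamination is modelled with a geometric decay of the
#' per-base damage probability from each fragment end: the probability that
#' an eligible base at terminal offset `i` (0-based) is deaminated is
#' `d0 * lam^i`, truncated to zero at offsets `>= window`. Single-stranded
#' libraries show C->T at both fragment ends; double-stranded libraries
#' show C->T at the 5' end and G->A at the 3' end.
#'
#' @param library_type "single_stranded" or "double_stranded".
#' @param d0 terminal (offset 0) deamination probability in \[0,1\].
#' @param lam per-offset geometric decay factor in (0,1).
#' @param window number of terminal positions subject to damage.
#' @return object of class `damage_params`.
#' @export
damage_params <- function(library_type = c("single_stranded", "double_stranded"),
                          d0 = 0.2, lam = 0.5, window = 25L) {
  library_type <- match.arg(library_type)
  stopifnot(d0 >= 0, d0 <= 1, lam > 0, lam < 1, window >= 1)
  structure(list(library_type = library_type, d0 = d0, lam = lam,
                 window = as.integer(window)),
            class = "damage_params")
}

damage_prob <- function(offset, dmg) {
  p <- dmg$d0 * dmg$lam^offset
  p[offset >= dmg$window] <- 0
  p
}

#' Simulation configuration for one sample's read set
#'
#' @param coverage target mean depth (total emitted bases / reference
#'   length). Museum aDNA libraries in this setting span roughly 6x-430x.
#' @param frag_len_meanlog,frag_len_sdlog lognormal fragment-length
#'   parameters (median `exp(meanlog)`); lengths truncated to \[15, 300\].
#' @param seq_error per-base sequencing error probability.
#' @param dup_rate fraction of fragments emitted twice (PCR duplicates).
#' @param base_qual constant Phred base quality for emitted reads.
#' @param qual_jitter integer half-width of optional uniform quality jitter.
#' @param seed RNG seed; fixed seed gives byte-identical output.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(coverage = 30, frag_len_meanlog = log(60),
                       frag_len_sdlog = 0.35, seq_error = 0.001,
                       dup_rate = 0.1, base_qual = 30L, qual_jitter = 0L,
                       seed = 1L) {
  stopifnot(coverage > 0, seq_error >= 0, seq_error <= 1,
            dup_rate >= 0, dup_rate <= 1, frag_len_sdlog > 0)
  structure(list(coverage = coverage, frag_len_meanlog = frag_len_meanlog,
                 frag_len_sdlog = frag_len_sdlog, seq_error = seq_error,
                 dup_rate = dup_rate, base_qual = as.integer(base_qual),
                 qual_jitter = as.integer(qual_jitter),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Mutate a reference into a haplotype with a fixed number of substitutions
#'
#' Places exactly `n_diffs` substitutions at distinct uniformly chosen
#' positions; each substituted base is drawn uniformly from the three
#' non-reference bases. The truth table of changes is carried with the
#' haplotype so downstream calls can be scored against it.
#'
#' @param ref a [mito_reference()].
#' @param n_diffs number of substitutions, `0 <= n_diffs <= length(ref)`.
#' @param seed RNG seed.
#' @param sample_id identifier for the resulting haplotype.
#' @return object of class `haplotype`: `sample_id`, `sequence`,
#'   `truth_diffs` (data.frame position/ref_base/alt_base, 1-based).
#' @export
mutate_reference <- function(ref, n_diffs, seed = 1L,
                             sample_id = sprintf("hap_%ddiff", n_diffs)) {
  stopifnot(inherits(ref, "mito_reference"))
  n_diffs <- as.integer(n_diffs)
  if (n_diffs < 0 || n_diffs > length(ref))
    stop("n_diffs must be between 0 and the reference length")
  set.seed(seed)
  seq <- ref$sequence
  if (n_diffs == 0L) {
    td <- data.frame(position = integer(0), ref_base = character(0),
                     alt_base = character(0), stringsAsFactors = FALSE)
  } else {
    pos <- sort(sample.int(length(ref), n_diffs))
    refb <- substring(seq, pos, pos)
    altb <- vapply(refb, function(b) sample(setdiff(DNA_BASES, b), 1L),
                   character(1), USE.NAMES = FALSE)
    ch <- strsplit(seq, "")[[1]]
    ch[pos] <- altb
    seq <- paste(ch, collapse = "")
    td <- data.frame(position = pos, ref_base = refb, alt_base = altb,
                     stringsAsFactors = FALSE)
  }
  structure(list(sample_id = sample_id, sequence = seq, truth_diffs = td),
            class = "haplotype")
}

# Draw fragment coordinates until total emitted bases (duplicates
# included) reach coverage * L.
draw_fragments <- function(L, cfg) {
  target <- cfg$coverage * L / (1 + cfg$dup_rate)
  n_guess <- ceiling(target / 45) + 50L
  lens <- integer(0)
  while (sum(lens) < target) {
    draw <- round(rlnorm(n_guess, cfg$frag_len_meanlog, cfg$frag_len_sdlog))
    draw <- pmin(pmax(draw, 15), 300)
    lens <- c(lens, as.integer(draw))
  }
  keep <- which(cumsum(lens) >= target)[1]
  lens <- lens[seq_len(keep)]
  n <- length(lens)
  data.frame(start = sample.int(L, n, replace = TRUE),
             len = lens,
             strand = ifelse(runif(n) < 0.5, "+", "-"),
             stringsAsFactors = FALSE)
}

#' Simulate damaged ancient-DNA reads from a haplotype
#'
#' Emulates the short-fragment, terminally deaminated read sets typical of
#' degraded museum specimens. Fragment lengths are truncated-lognormal,
#' placement is uniform on the circle (fragments may wrap the origin),
#' strand is uniform. Deamination is applied first (template level), PCR
#' duplicates copy the damaged template, then sequencing error is drawn
#' independently per emitted read. A truth table records every fragment's
#' origin and its damage/error events.
#'
#' @param hap a [mutate_reference()] haplotype.
#' @param cfg a [sim_config()].
#' @param dmg a [damage_params()].
#' @return list with `reads` (data.frame read_id/sample_id/seq/qual) and
#'   `truth` (data.frame fragment_id/sample/start/end/strand/
#'   damage_positions/n_damage/n_errors/duplicate_of).
#' @export
simulate_reads <- function(hap, cfg, dmg) {
  stopifnot(inherits(hap, "haplotype"), inherits(cfg, "sim_config"),
            inherits(dmg, "damage_params"))
  set.seed(cfg$seed)
  L <- nchar(hap$sequence)
  doubled <- paste0(hap$sequence, hap$sequence)
  fr <- draw_fragments(L, cfg)
  n <- nrow(fr)
  fr$end <- fr$start + fr$len - 1L        # may exceed L (wrap-around)
  mol <- substring(doubled, fr$start, fr$end)
  neg <- fr$strand == "-"
  mol[neg] <- revcomp(mol[neg])           # molecule in read orientation

  # --- template-level deamination on the flat base vector ---------------
  flat <- strsplit(paste(mol, collapse = ""), "")[[1]]
  ridx <- rep.int(seq_len(n), fr$len)
  off5 <- sequence(fr$len) - 1L
  off3 <- rep.int(fr$len, fr$len) - sequence(fr$len)
  p5 <- damage_prob(off5, dmg)
  hit5 <- flat == "C" & runif(length(flat)) < p5
  flat[hit5] <- "T"
  if (dmg$library_type == "single_stranded") {
    p3 <- damage_prob(off3, dmg)
    hit3 <- flat == "C" & runif(length(flat)) < p3
    flat[hit3] <- "T"
  } else {
    p3 <- damage_prob(off3, dmg)
    hit3 <- flat == "G" & runif(length(flat)) < p3
    flat[hit3] <- "A"
  }
  dmg_hit <- hit5 | hit3
  cat_seq <- paste(flat, collapse = "")
  bnd_end <- cumsum(fr$len)
  bnd_start <- bnd_end - fr$len + 1L
  mol <- substring(cat_seq, bnd_start, bnd_end)
  dmg_pos <- vapply(seq_len(n), function(i) {
    w <- which(dmg_hit[bnd_start[i]:bnd_end[i]])
    paste(w - 1L, collapse = ",")        # read-orientation offsets
  }, character(1))
  n_dmg <- as.integer(rowsum(as.integer(dmg_hit), ridx))

  # --- PCR duplicates copy the damaged template -------------------------
  n_dup <- round(cfg$dup_rate * n)
  dup_of <- rep(NA_integer_, n)
  if (n_dup > 0) {
    src <- sample.int(n, n_dup)
    fr <- rbind(fr, fr[src, , drop = FALSE])
    mol <- c(mol, mol[src])
    dmg_pos <- c(dmg_pos, dmg_pos[src])
    n_dmg <- c(n_dmg, n_dmg[src])
    dup_of <- c(dup_of, src)
  }
  m <- length(mol)

  # --- per-read sequencing error ----------------------------------------
  flat <- strsplit(paste(mol, collapse = ""), "")[[1]]
  ridx <- rep.int(seq_len(m), fr$len)
  err <- runif(length(flat)) < cfg$seq_error
  if (any(err)) {
    cur <- flat[err]
    shift <- sample.int(3L, sum(err), replace = TRUE)
    cur_i <- match(cur, DNA_BASES)
    flat[err] <- DNA_BASES[((cur_i - 1L + shift) %% 4L) + 1L]
  }
  cat_seq <- paste(flat, collapse = "")
  bnd_end <- cumsum(fr$len)
  bnd_start <- bnd_end - fr$len + 1L
  seqs <- substring(cat_seq, bnd_start, bnd_end)
  n_err <- as.integer(rowsum(as.integer(err), ridx))

  # --- qualities --------------------------------------------------------
  if (cfg$qual_jitter > 0) {
    qs <- vapply(fr$len, function(l)
      int_to_qual(cfg$base_qual +
                    sample.int(2L * cfg$qual_jitter + 1L, l, replace = TRUE) -
                    cfg$qual_jitter - 1L),
      character(1))
  } else {
    qchar <- rawToChar(as.raw(cfg$base_qual + 33L))
    qs <- strrep(qchar, fr$len)
  }

  read_id <- sprintf("%s_frag%06d%s", hap$sample_id, seq_len(m),
                     ifelse(is.na(dup_of), "", "_dup"))
  list(
    reads = data.frame(read_id = read_id, sample_id = hap$sample_id,
                       seq = seqs, qual = qs, stringsAsFactors = FALSE),
    truth = data.frame(fragment_id = read_id, sample = hap$sample_id,
                       start = fr$start, end = fr$end, strand = fr$strand,
                       damage_positions = dmg_pos, n_damage = n_dmg,
                       n_errors = n_err, duplicate_of = dup_of,
                       stringsAsFactors = FALSE)
  )
}

#' Simulate a multi-sample identity-matching study
#'
#' Generates per-sample haplotypes at given substitution distances from the
#' reference, with an optional planted identical pair (two samples sharing
#' one haplotype -- the "organ" and the "skin" of the same individual),
#' then simulates damaged reads for every sample. Per-sample RNG streams
#' are derived from the root seed by fixed offsets, so adding a sample
#' never perturbs earlier samples.
#'
#' @param ref a [mito_reference()].
#' @param sample_ids character vector of sample names.
#' @param diffs_per_sample integer vector, substitutions from the reference
#'   for each sample (the planted pair's second member ignores its entry).
#' @param duplicate_pair length-2 character vector naming the two samples
#'   that share a haplotype, or NULL.
#' @param coverage scalar or per-sample vector of mean depths.
#' @param dmg a [damage_params()] shared by all samples, or a list of one
#'   per sample.
#' @param cfg_template a [sim_config()] supplying non-coverage settings.
#' @param seed root RNG seed.
#' @return list with `haplotypes` (named list), `reads` (named list of
#'   read data.frames), `truth` (named list), `sample_ids`.
#' @export
simulate_study <- function(ref, sample_ids, diffs_per_sample,
                           duplicate_pair = NULL, coverage = 30,
                           dmg = damage_params(), cfg_template = sim_config(),
                           seed = 1L) {
  stopifnot(length(sample_ids) == length(diffs_per_sample),
            !anyDuplicated(sample_ids))
  if (!is.null(duplicate_pair)) {
    stopifnot(length(duplicate_pair) == 2L,
              all(duplicate_pair %in% sample_ids))
  }
  n <- length(sample_ids)
  coverage <- rep_len(coverage, n)
  if (inherits(dmg, "damage_params")) dmg <- rep(list(dmg), n)
  haps <- vector("list", n)
  names(haps) <- sample_ids
  for (i in seq_len(n)) {
    hseed <- (seed + 7919L * i) %% .Machine$integer.max
    haps[[i]] <- mutate_reference(ref, diffs_per_sample[i], seed = hseed,
                                  sample_id = sample_ids[i])
  }
  if (!is.null(duplicate_pair)) {
    a <- duplicate_pair[1]; b <- duplicate_pair[2]
    haps[[b]]$sequence <- haps[[a]]$sequence
    haps[[b]]$truth_diffs <- haps[[a]]$truth_diffs
  }
  reads <- truth <- vector("list", n)
  names(reads) <- names(truth) <- sample_ids
  for (i in seq_len(n)) {
    cfg <- cfg_template
    cfg$coverage <- coverage[i]
    cfg$seed <- (seed + 104729L * i) %% .Machine$integer.max
    sim <- simulate_reads(haps[[i]], cfg, dmg[[i]])
    reads[[i]] <- sim$reads
    truth[[i]] <- sim$truth
  }
  list(haplotypes = haps, reads = reads, truth = truth,
       sample_ids = sample_ids)
}

#' Write simulated reads to FASTQ (Phred+33)
#' @param reads data.frame from [simulate_reads()].
#' @param path output FASTQ path.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$read_id, "\n", reads$seq, "\n+\n", reads$qual),
             con, sep = "\n")
  invisible(path)
}

#' Read a FASTQ file into the pipeline's read table
#' @param path FASTQ path.
#' @param sample_id sample name to attach.
#' @export
read_fastq <- function(path, sample_id = basename(path)) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq",
                                     with.qualities = TRUE)
  data.frame(read_id = names(ss), sample_id = sample_id,
             seq = as.character(ss),
             qual = as.character(S4Vectors::mcols(ss)$qualities),
             stringsAsFactors = FALSE)
}
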