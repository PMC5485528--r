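#' Read filtering parameters
#'
#' Bundles the read-level thresholds used throughout processing: minimum
#' retained read length 25 bp, minimum mate overlap 11 bp for collapsing,
#' adapter mismatch rate 0.333, and the MAPQ >= 20 gate.
#'
#' @param min_len minimum retained read length (bp).
#' @param min_overlap minimum mate overlap for collapsing (bp).
#' @param adapter_mm_rate maximum mismatch fraction for an adapter match.
#' @param min_mapq minimum retained mapping quality (reads with MAPQ below
#'   this are removed; a read at exactly `min_mapq` is kept).
#' @return object of class `read_filter_params`.
#' @export
read_filter_params <- function(min_len = 25L, min_overlap = 11L,
                               adapter_mm_rate = 0.333, min_mapq = 20L) {
  stopifnot(min_len >= 1, min_overlap >= 1,
            adapter_mm_rate >= 0, adapter_mm_rate < 1, min_mapq >= 0)
  structure(list(min_len = as.integer(min_len),
                 min_overlap = as.integer(min_overlap),
                 adapter_mm_rate = adapter_mm_rate,
                 min_mapq = as.integer(min_mapq)),
            class = "read_filter_params")
}

# Default Illumina-style adapter pair (configurable in trim_collapse).
DEFAULT_ADAPTER1 <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC"
DEFAULT_ADAPTER2 <- "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGTA"

# Trim an adapter from the 3' end: the leftmost position whose suffix
# matches a prefix of the adapter with mismatch fraction <= mm_rate wins.
# Matches shorter than min_ov bases are ignored so that chance agreement
# of a read's final few bases with the adapter start does not nibble
# genuine sequence.
trim_adapter_one <- function(seq, adapter, mm_rate, min_ov = 9L) {
  L <- nchar(seq); A <- nchar(adapter)
  for (p in seq_len(L)) {
    ov <- min(L - p + 1L, A)
    if (ov < min_ov) break
    s <- substr(seq, p, p + ov - 1L)
    a <- substr(adapter, 1L, ov)
    if (count_mismatches(s, a) / ov <= mm_rate) return(p - 1L)
  }
  L
}

# Align mate 2 (already reverse-complemented into read-1 orientation)
# against mate 1 over every shift, including negative shifts where the
# fragment is shorter than the reads (adapter read-through): the merged
# read spans from the start of read 1 to the end of mate 2, so overhangs
# on the wrong side -- read-through into adapter -- are dropped.
merge_overlap <- function(s1, q1, s2, q2, min_overlap) {
  l1 <- nchar(s1); l2 <- nchar(s2)
  best <- NULL; best_score <- 0L
  for (delta in seq(-(l2 - 1L), l1 - 1L)) {
    a1 <- max(1L, 1L + delta)
    a2 <- min(l1, l2 + delta)
    o <- a2 - a1 + 1L
    if (o <= 0L) next
    mm <- count_mismatches(substr(s1, a1, a2),
                           substr(s2, a1 - delta, a2 - delta))
    score <- (o - mm) - mm
    if (score > best_score) {
      best_score <- score
      best <- list(delta = delta, a1 = a1, a2 = a2, o = o)
    }
  }
  if (is.null(best) || best$o < min_overlap) return(NULL)
  delta <- best$delta; a1 <- best$a1; a2 <- best$a2; o <- best$o
  q1i <- qual_to_int(q1)[[1]]; q2i <- qual_to_int(q2)[[1]]
  b1 <- strsplit(substr(s1, a1, a2), "")[[1]]
  b2 <- strsplit(substr(s2, a1 - delta, a2 - delta), "")[[1]]
  oq1 <- q1i[a1:a2]; oq2 <- q2i[(a1 - delta):(a2 - delta)]
  agree <- b1 == b2
  mb <- ifelse(agree, b1, ifelse(oq1 >= oq2, b1, b2))
  mq <- ifelse(agree, pmin(oq1 + oq2, 41L), abs(oq1 - oq2))
  pre_b <- if (delta > 0L) substr(s1, 1L, delta) else ""
  pre_q <- if (delta > 0L) q1i[seq_len(delta)] else integer(0)
  post_b <- if (l2 + delta > l1) substr(s2, a2 - delta + 1L, l2) else ""
  post_q <- if (l2 + delta > l1) q2i[(a2 - delta + 1L):l2] else integer(0)
  list(seq = paste0(pre_b, paste(mb, collapse = ""), post_b),
       qual = int_to_qual(c(pre_q, mq, post_q)))
}

#' Adapter-trim and collapse paired-end reads
#'
#' Removes adapter read-through from the 3' ends of both mates (semi-global
#' match, mismatch fraction at most `adapter_mm_rate`), then merges mate
#' pairs whose best overlap is at least `min_overlap` bases into a single
#' read: agreeing bases get quality `min(q1+q2, 41)`, disagreeing bases
#' keep the higher-quality base at quality `|q1-q2|`. Output reads shorter
#' than `min_len` are discarded; pairs that fail to overlap are emitted
#' unmerged (both mates, mate 2 reverse-complemented into reference
#' orientation).
#'
#' @param pairs list with elements `r1` and `r2`, each a read data.frame
#'   (`read_id`, `sample_id`, `seq`, `qual`), row-matched mates.
#' @param params a [read_filter_params()].
#' @param adapters length-2 character vector of adapter sequences.
#' @return read data.frame of processed reads.
#' @export
trim_collapse <- function(pairs, params = read_filter_params(),
                          adapters = c(DEFAULT_ADAPTER1, DEFAULT_ADAPTER2)) {
  r1 <- pairs$r1; r2 <- pairs$r2
  stopifnot(nrow(r1) == nrow(r2))
  bad <- nchar(r1$seq) != nchar(r1$qual) | nchar(r2$seq) != nchar(r2$qual)
  if (any(bad))
    stop("malformed FASTQ record (seq/qual length mismatch) at pair ",
         which(bad)[1])
  out <- vector("list", nrow(r1))
  for (i in seq_len(nrow(r1))) {
    t1 <- trim_adapter_one(r1$seq[i], adapters[1], params$adapter_mm_rate)
    t2 <- trim_adapter_one(r2$seq[i], adapters[2], params$adapter_mm_rate)
    s1 <- substr(r1$seq[i], 1L, t1); q1 <- substr(r1$qual[i], 1L, t1)
    s2 <- substr(r2$seq[i], 1L, t2); q2 <- substr(r2$qual[i], 1L, t2)
    s2rc <- revcomp(s2); q2r <- rev_string(q2)
    m <- if (nchar(s1) > 0L && nchar(s2) > 0L)
      merge_overlap(s1, q1, s2rc, q2r, params$min_overlap) else NULL
    if (!is.null(m)) {
      if (nchar(m$seq) >= params$min_len)
        out[[i]] <- data.frame(read_id = paste0(r1$read_id[i], "_M"),
                               sample_id = r1$sample_id[i],
                               seq = m$seq, qual = m$qual,
                               stringsAsFactors = FALSE)
    } else {
      keep1 <- nchar(s1) >= params$min_len
      keep2 <- nchar(s2) >= params$min_len
      rows <- list()
      if (keep1) rows <- c(rows, list(data.frame(
        read_id = paste0(r1$read_id[i], "_1"), sample_id = r1$sample_id[i],
        seq = s1, qual = q1, stringsAsFactors = FALSE)))
      if (keep2) rows <- c(rows, list(data.frame(
        read_id = paste0(r2$read_id[i], "_2"), sample_id = r2$sample_id[i],
        seq = s2rc, qual = q2r, stringsAsFactors = FALSE)))
      if (length(rows)) out[[i]] <- do.call(rbind, rows)
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(read_id = character(0), sample_id = character(0),
                      seq = character(0), qual = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# k-mer position index over the doubled reference (hashed environment).
kmer_index <- function(doubled, k) {
  n <- nchar(doubled) - k + 1L
  if (n < 1L) return(list2env(list(), hash = TRUE))
  kmers <- substring(doubled, seq_len(n), seq_len(n) + k - 1L)
  list2env(split(seq_len(n), kmers), hash = TRUE,
           size = length(unique(kmers)))
}

#' Map reads gaplessly to a circular reference
#'
#' Seed-and-extend mapper for the substitution-only mitogenome setting:
#' exact k-mer seeds (k = 13) at three offsets per read are looked up in an
#' index of the doubled reference (which resolves circularity), candidate
#' placements are scored by mismatch count on both strands, and the best
#' placement is reported. MAPQ is 60 for a unique candidate, 0 for a tied
#' best, otherwise `min(60, 10 * (mm2 - mm1))`. Reads whose best placement
#' has mismatch fraction above `max_mm_frac` are dropped (unmapped).
#' Alignments are gapless; `start` is 1-based on the reference and `end`
#' may exceed the reference length for origin-spanning reads.
#'
#' @param reads read data.frame (`read_id`, `sample_id`, `seq`, `qual`).
#' @param ref a [mito_reference()].
#' @param k seed length.
#' @param max_mm_frac maximum mismatch fraction for a reported alignment.
#' @return alignment data.frame of class `read_alignments`: `read_id`,
#'   `sample_id`, `start`, `end`, `strand`, `seq`, `qual` (both in
#'   reference orientation), `mapq`, `nm`.
#' @export
map_reads <- function(reads, ref, k = 13L, max_mm_frac = 0.1) {
  stopifnot(inherits(ref, "mito_reference"))
  if (length(ref) == 0L) stop("empty reference")
  L <- length(ref)
  doubled <- paste0(ref$sequence, ref$sequence)
  idx <- kmer_index(doubled, k)
  empty <- data.frame(read_id = character(0), sample_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), seq = character(0),
                      qual = character(0), mapq = integer(0),
                      nm = integer(0), stringsAsFactors = FALSE)
  if (nrow(reads) == 0L) return(structure(empty, class = c("read_alignments", "data.frame")))

  gather_candidates <- function(seqs, strand) {
    lens <- nchar(seqs)
    usable <- which(lens >= k)
    cand <- list()
    for (nm_off in c("l", "m", "r")) {
      off <- switch(nm_off,
                    l = rep(0L, length(usable)),
                    m = as.integer((lens[usable] - k) %/% 2L),
                    r = lens[usable] - k)
      seeds <- substring(seqs[usable], off + 1L, off + k)
      hits <- mget(seeds, envir = idx, ifnotfound = list(integer(0)))
      nh <- lengths(hits)
      if (sum(nh) == 0L) next
      cand[[nm_off]] <- data.frame(
        read = rep.int(usable, nh),
        start = unlist(hits, use.names = FALSE) - rep.int(off, nh),
        stringsAsFactors = FALSE)
    }
    if (!length(cand)) return(NULL)
    cc <- do.call(rbind, cand)
    cc <- cc[cc$start >= 1L & cc$start <= L &
               cc$start + lens[cc$read] - 1L <= 2L * L, , drop = FALSE]
    if (!nrow(cc)) return(NULL)
    cc$strand <- strand
    cc <- unique(cc)
    cc$mm <- count_mismatches(seqs[cc$read],
                              substring(doubled, cc$start,
                                        cc$start + lens[cc$read] - 1L))
    cc
  }

  fwd <- gather_candidates(reads$seq, "+")
  rcseq <- revcomp(reads$seq)
  rev <- gather_candidates(rcseq, "-")
  cc <- rbind(fwd, rev)
  if (is.null(cc) || !nrow(cc)) return(structure(empty, class = c("read_alignments", "data.frame")))

  o <- order(cc$read, cc$mm, cc$start, cc$strand)
  cc <- cc[o, , drop = FALSE]
  rk <- stats::ave(cc$mm, cc$read, FUN = seq_along)
  best <- cc[rk == 1L, , drop = FALSE]
  second <- cc[rk == 2L, , drop = FALSE]
  mm2 <- rep(NA_integer_, nrow(best))
  mm2[match(second$read, best$read)] <- second$mm
  lens <- nchar(reads$seq)[best$read]
  mapq <- ifelse(is.na(mm2), 60L,
                 ifelse(mm2 == best$mm, 0L,
                        pmin(60L, 10L * (mm2 - best$mm))))
  keep <- best$mm / lens <= max_mm_frac
  best <- best[keep, , drop = FALSE]
  mapq <- mapq[keep]
  neg <- best$strand == "-"
  seq_out <- ifelse(neg, rcseq[best$read], reads$seq[best$read])
  qual_out <- reads$qual[best$read]
  qual_out[neg] <- rev_string(qual_out[neg])
  res <- data.frame(read_id = reads$read_id[best$read],
                    sample_id = reads$sample_id[best$read],
                    start = best$start,
                    end = best$start + nchar(seq_out) - 1L,
                    strand = best$strand, seq = seq_out, qual = qual_out,
                    mapq = as.integer(mapq), nm = best$mm,
                    stringsAsFactors = FALSE)
  res <- res[order(res$start, res$end, res$strand, res$read_id), ]
  rownames(res) <- NULL
  structure(res, class = c("read_alignments", "data.frame"))
}

#' Remove alignments below the MAPQ threshold
#'
#' Alignments with MAPQ below `min_mapq` are removed; an alignment at
#' exactly the threshold is retained.
#'
#' @param alns alignment data.frame from [map_reads()].
#' @param params a [read_filter_params()].
#' @export
filter_mapq <- function(alns, params = read_filter_params()) {
  alns[alns$mapq >= params$min_mapq, , drop = FALSE]
}

#' Remove PCR duplicates
#'
#' Among alignments sharing (start, end, strand), only the one with the
#' highest total base quality is retained (ties broken by lexicographically
#' smallest read id). Input must be coordinate-sorted.
#'
#' @param alns alignment data.frame sorted by (start, end, strand).
#' @export
dedup <- function(alns) {
  if (nrow(alns) == 0L) return(alns)
  o <- order(alns$start, alns$end, alns$strand)
  if (!identical(o, seq_len(nrow(alns))))
    stop("dedup requires input sorted by (start, end, strand)")
  qsum <- vapply(qual_to_int(alns$qual), sum, numeric(1))
  key <- paste(alns$start, alns$end, alns$strand, sep = "\r")
  ord <- order(key, -qsum, alns$read_id)
  keep <- ord[!duplicated(key[ord])]
  res <- alns[sort(keep), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Long-format per-base expansion of a set of alignments (positions reduced
# modulo the reference length for wrap-around reads).
expand_bases <- function(alns, L) {
  lens <- alns$end - alns$start + 1L
  pos <- ((rep.int(alns$start, lens) + sequence(lens) - 2L) %% L) + 1L
  base <- strsplit(paste(alns$seq, collapse = ""), "")[[1]]
  qual <- as.integer(charToRaw(paste(alns$qual, collapse = ""))) - 33L
  list(pos = pos, base = base, qual = qual,
       aln = rep.int(seq_len(nrow(alns)), lens),
       off5 = sequence(lens) - 1L,
       off3 = rep.int(lens, lens) - sequence(lens),
       strand = rep.int(alns$strand, lens))
}

#' Build a per-position pileup over the reference
#'
#' One column per reference position; wrap-around alignments contribute to
#' positions modulo the reference length. The coverage summary is total
#' aligned bases divided by reference length, reported to 2 decimals.
#'
#' @param alns MAPQ-filtered, deduplicated alignments.
#' @param ref a [mito_reference()].
#' @return object of class `mito_pileup`: `counts` (L x 4 matrix), `depth`
#'   (length-L integer), `coverage`, and the long per-base vectors used by
#'   the genotype caller.
#' @export
pileup <- function(alns, ref) {
  L <- length(ref)
  eb <- if (nrow(alns)) expand_bases(alns, L) else
    list(pos = integer(0), base = character(0), qual = integer(0))
  counts <- matrix(0L, nrow = L, ncol = 4L,
                   dimnames = list(NULL, DNA_BASES))
  if (length(eb$pos)) {
    tab <- table(factor(eb$pos, levels = seq_len(L)),
                 factor(eb$base, levels = DNA_BASES))
    counts <- matrix(as.integer(tab), nrow = L, ncol = 4L,
                     dimnames = list(NULL, DNA_BASES))
  }
  depth <- as.integer(rowSums(counts))
  structure(list(counts = counts, depth = depth,
                 coverage = round(sum(depth) / L, 2),
                 bases = eb, ref_length = L),
            class = "mito_pileup")
}

#' Extract one pileup column
#' @param p a [pileup()] object.
#' @param position 1-based reference position.
#' @return list with `position`, `base_counts`, `quals_per_base`, `depth`.
#' @export
pileup_column <- function(p, position) {
  sel <- p$bases$pos == position
  quals <- split(p$bases$qual[sel],
                 factor(p$bases$base[sel], levels = DNA_BASES))
  list(position = position, base_counts = p$counts[position, ],
       quals_per_base = quals, depth = p$depth[position])
}

#' Write gapless alignments as SAM
#' @param alns alignment data.frame.
#' @param ref a [mito_reference()].
#' @param path output path.
#' @export
write_sam <- function(alns, ref, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", ref$id, length(ref))), con)
  if (nrow(alns)) {
    flag <- ifelse(alns$strand == "-", 16L, 0L)
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s\tNM:i:%d",
                       alns$read_id, flag, ref$id, alns$start, alns$mapq,
                       nchar(alns$seq), alns$seq, alns$qual, alns$nm), con)
  }
  invisible(path)
}

#' Read coordinate-sorted gapless SAM alignments
#'
#' Ingests externally produced alignments (gapless CIGAR only) so the
#' built-in mapper can be bypassed.
#'
#' @param path SAM file.
#' @param sample_id sample name to attach.
#' @export
read_sam <- function(path, sample_id = basename(path)) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "@")]
  if (!length(ln))
    return(structure(data.frame(read_id = character(0),
                                sample_id = character(0), start = integer(0),
                                end = integer(0), strand = character(0),
                                seq = character(0), qual = character(0),
                                mapq = integer(0), nm = integer(0),
                                stringsAsFactors = FALSE),
                     class = c("read_alignments", "data.frame")))
  f <- strsplit(ln, "\t")
  get <- function(i) vapply(f, `[[`, character(1), i)
  cig <- get(6)
  if (any(!grepl("^[0-9]+M$", cig)))
    stop("only gapless (xM) CIGAR strings are supported")
  seqs <- get(10)
  nmtag <- vapply(f, function(x) {
    g <- grep("^NM:i:", x, value = TRUE)
    if (length(g)) g[1] else "NM:i:0"
  }, character(1))
  res <- data.frame(read_id = get(1), sample_id = sample_id,
                    start = as.integer(get(4)),
                    end = as.integer(get(4)) + nchar(seqs) - 1L,
                    strand = ifelse(bitwAnd(as.integer(get(2)), 16L) > 0L,
                                    "-", "+"),
                    seq = seqs, qual = get(11),
                    mapq = as.integer(get(5)),
                    nm = as.integer(sub("^NM:i:", "", nmtag)),
                    stringsAsFactors = FALSE)
  structure(res, class = c("read_alignments", "data.frame"))
}
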