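# Build a mate pair from a fragment: read1 from the 5' end, read2
# reverse-complemented from the 3' end, optional adapter read-through.
make_pair <- function(frag, rlen, adapter1 = "", adapter2 = "", q = 35L) {
  flen <- nchar(frag)
  r1 <- substr(frag, 1, min(rlen, flen))
  r2 <- oracle_revcomp(substr(frag, max(1, flen - rlen + 1), flen))
  if (nchar(r1) < rlen) r1 <- paste0(r1, substr(adapter1, 1, rlen - nchar(r1)))
  if (nchar(r2) < rlen) r2 <- paste0(r2, substr(adapter2, 1, rlen - nchar(r2)))
  qs <- strrep(rawToChar(as.raw(q + 33L)), nchar(r1))
  list(r1 = data.frame(read_id = "p1", sample_id = "s", seq = r1,
                       qual = qs, stringsAsFactors = FALSE),
       r2 = data.frame(read_id = "p1", sample_id = "s", seq = r2,
                       qual = strrep(rawToChar(as.raw(q + 33L)), nchar(r2)),
                       stringsAsFactors = FALSE))
}

ADP1 <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC"
ADP2 <- "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGTA"

test_that("overlapping mates collapse into one read of the fragment length", {
  frag <- rand_dna(60, seed = 21)
  pr <- make_pair(frag, 40)           # overlap 40+40-60 = 20
  out <- trim_collapse(pr)
  expect_identical(nrow(out), 1L)
  expect_identical(out$seq, frag)
  expect_identical(nchar(out$seq), 40L + 40L - 20L)
  # agreeing overlap bases get summed quality capped at 41
  qi <- as.integer(charToRaw(out$qual)) - 33L
  expect_true(all(qi[21:40] == 41L))
  expect_true(all(qi[1:20] == 35L))
})

test_that("adapter read-through is removed before collapsing", {
  frag <- rand_dna(30, seed = 22)
  pr <- make_pair(frag, 42, ADP1, ADP2)
  out <- trim_collapse(pr)
  expect_identical(nrow(out), 1L)
  expect_identical(out$seq, frag)
})

test_that("collapsed reads below 25 bp are discarded, 25 bp kept", {
  frag24 <- rand_dna(24, seed = 23)
  out24 <- trim_collapse(make_pair(frag24, 30, ADP1, ADP2))
  expect_identical(nrow(out24), 0L)
  frag25 <- rand_dna(25, seed = 24)
  out25 <- trim_collapse(make_pair(frag25, 30, ADP1, ADP2))
  expect_identical(out25$seq, frag25)
})

test_that("pairs overlapping by only 10 bp are emitted unmerged", {
  frag <- rand_dna(70, seed = 25)
  pr <- make_pair(frag, 40)           # best overlap 40+40-70 = 10 < 11
  out <- trim_collapse(pr)
  expect_identical(nrow(out), 2L)
  expect_setequal(out$seq, c(substr(frag, 1, 40), substr(frag, 31, 70)))
})

test_that("malformed records are rejected with the pair offset", {
  pr <- make_pair(rand_dna(50, seed = 26), 30)
  pr$r1$qual <- substr(pr$r1$qual, 1, 10)
  expect_error(trim_collapse(pr), "malformed FASTQ record.*pair 1")
})

test_that("exact substrings map to their origin with MAPQ 60", {
  ref <- random_reference(800, seed = 31)
  read <- data.frame(read_id = "r", sample_id = "s",
                     seq = substr(ref$sequence, 101, 130),
                     qual = strrep("I", 30), stringsAsFactors = FALSE)
  aln <- map_reads(read, ref)
  expect_identical(aln$start, 101L)
  expect_identical(aln$end, 130L)
  expect_identical(aln$strand, "+")
  expect_identical(aln$mapq, 60L)
  expect_identical(aln$nm, 0L)
  expect_error(map_reads(read, mito_reference("e", "A")), NA)
})

test_that("origin-spanning reads map across the circular junction", {
  ref <- random_reference(500, seed = 32)
  doubled <- paste0(ref$sequence, ref$sequence)
  read_seq <- substr(doubled, 491, 530)      # wraps the origin
  aln <- map_reads(data.frame(read_id = "w", sample_id = "s",
                              seq = read_seq, qual = strrep("I", 40),
                              stringsAsFactors = FALSE), ref)
  expect_identical(aln$start, 491L)
  expect_identical(aln$end, 530L)            # > reference length
  expect_identical(aln$nm, 0L)
  expect_identical(substring(doubled, aln$start, aln$end), read_seq)
})

test_that("a read present reverse-complemented elsewhere gets MAPQ 0", {
  set.seed(33)
  block <- rand_dna(40, seed = 33)
  left <- rand_dna(100, seed = 34)
  mid <- rand_dna(100, seed = 35)
  right <- rand_dna(100, seed = 36)
  ref <- mito_reference("rep", paste0(left, block, mid,
                                      oracle_revcomp(block), right))
  aln <- map_reads(data.frame(read_id = "r", sample_id = "s", seq = block,
                              qual = strrep("I", 40),
                              stringsAsFactors = FALSE), ref)
  expect_identical(nrow(aln), 1L)
  expect_identical(aln$mapq, 0L)
})

test_that("MAPQ filter keeps exactly the alignments at or above 20", {
  alns <- data.frame(read_id = c("a", "b", "c"), sample_id = "s",
                     start = c(1L, 5L, 9L), end = c(30L, 34L, 38L),
                     strand = "+", seq = strrep("A", 30),
                     qual = strrep("I", 30), mapq = c(19L, 20L, 60L),
                     nm = 0L, stringsAsFactors = FALSE)
  kept <- filter_mapq(alns)
  expect_setequal(kept$read_id, c("b", "c"))
  expect_identical(nrow(filter_mapq(alns[0, ])), 0L)
})

test_that("dedup keeps one best read per coordinate group and is idempotent", {
  q_hi <- strrep("I", 20); q_lo <- strrep("5", 20)
  alns <- data.frame(read_id = c("a2", "a1", "b"), sample_id = "s",
                     start = c(10L, 10L, 50L), end = c(29L, 29L, 69L),
                     strand = c("+", "+", "-"), seq = strrep("A", 20),
                     qual = c(q_lo, q_hi, q_hi), mapq = 60L, nm = 0L,
                     stringsAsFactors = FALSE)
  out <- dedup(alns)
  expect_identical(nrow(out), 2L)
  expect_setequal(out$read_id, c("a1", "b"))    # higher quality survives
  expect_identical(dedup(out), out)             # idempotent
  # quality ties break to the lexicographically smallest read id
  alns$qual <- q_hi
  expect_true("a1" %in% dedup(alns)$read_id)
  # distinct coordinates all survive
  alns$start <- c(1L, 2L, 3L); alns$end <- alns$start + 19L
  expect_identical(nrow(dedup(alns[order(alns$start), ])), 3L)
  expect_error(dedup(alns[c(3, 1, 2), ]), "sorted")
})

test_that("pileup depths match the interval-stabbing oracle", {
  ref <- random_reference(200, seed = 41)
  set.seed(42)
  n <- 40
  starts <- sample.int(200, n, replace = TRUE)
  lens <- sample(25:60, n, replace = TRUE)
  alns <- data.frame(read_id = sprintf("r%02d", seq_len(n)), sample_id = "s",
                     start = starts, end = starts + lens - 1L,
                     strand = sample(c("+", "-"), n, replace = TRUE),
                     seq = vapply(lens, function(l) rand_dna(l, l), character(1)),
                     qual = vapply(lens, function(l) strrep("I", l), character(1)),
                     mapq = 60L, nm = 0L, stringsAsFactors = FALSE)
  alns <- alns[order(alns$start, alns$end, alns$strand), ]
  p <- pileup(alns, ref)
  expect_identical(p$depth, oracle_depth(alns$start, alns$end, 200L))
  expect_identical(sum(p$depth), sum(lens))   # total bases conserved
})

test_that("coverage summary is total aligned bases over reference length", {
  ref <- random_reference(1000, seed = 43)
  alns <- data.frame(read_id = sprintf("r%d", 1:10), sample_id = "s",
                     start = seq(1L, 901L, by = 100L),
                     end = seq(50L, 950L, by = 100L), strand = "+",
                     seq = strrep("A", 50), qual = strrep("I", 50),
                     mapq = 60L, nm = 0L, stringsAsFactors = FALSE)
  expect_identical(pileup(alns, ref)$coverage, 0.50)
})

test_that("clean simulated reads recover their true origin", {
  ref <- random_reference(3000, seed = 44)
  hap <- mutate_reference(ref, 0, seed = 1, sample_id = "s")
  sim <- simulate_reads(hap, sim_config(coverage = 15, seed = 9,
                                        seq_error = 0, dup_rate = 0),
                        damage_params(d0 = 0))
  keep <- nchar(sim$reads$seq) >= 25
  reads <- sim$reads[keep, ]
  truth <- sim$truth[keep, ]
  alns <- map_reads(reads, ref)
  m <- match(alns$read_id, truth$fragment_id)
  uniq <- alns$mapq > 0L
  ok <- alns$start[uniq] == truth$start[m][uniq] &
    alns$strand[uniq] == truth$strand[m][uniq]
  expect_gte(mean(ok), 0.99)
})

test_that("alignments round-trip through SAM", {
  ref <- random_reference(400, seed = 45)
  reads <- data.frame(read_id = c("a", "b"), sample_id = "s",
                      seq = c(substr(ref$sequence, 11, 40),
                              oracle_revcomp(substr(ref$sequence, 101, 140))),
                      qual = c(strrep("I", 30), strrep("5", 40)),
                      stringsAsFactors = FALSE)
  alns <- map_reads(reads, ref)
  f <- tempfile(fileext = ".sam")
  write_sam(alns, ref, f)
  back <- read_sam(f, sample_id = "s")
  for (col in c("read_id", "start", "end", "strand", "seq", "qual", "mapq", "nm"))
    expect_identical(back[[col]], alns[[col]])
})
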