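#' Pipeline configuration
#'
#' Validates and freezes the options for an end-to-end run. Unknown
#' fields are rejected. Samples can carry in-memory read tables (the
#' simulation path) or FASTQ/SAM paths.
#'
#' @param reference a [mito_reference()] or path to a FASTA file.
#' @param samples named list; each element a list with optional `reads`
#'   (read data.frame), `fastq` (path), `sam` (path) -- exactly one -- and
#'   `library_type` ("single_stranded" default or "double_stranded").
#' @param tiers character subset of c("relaxed", "strict").
#' @param damage_window terminal offsets profiled for deamination.
#' @param min_overlap minimum shared positions for an identity match.
#' @param phylo a [phylo_params()] or NULL to skip tree building.
#' @param read_params a [read_filter_params()].
#' @param out_dir output directory or NULL for in-memory results only.
#' @param seed run seed (logged; the pipeline itself is deterministic
#'   given its inputs except for bootstrap resampling).
#' @return validated config of class `pipeline_config`.
#' @export
pipeline_config <- function(reference, samples, tiers = c("relaxed", "strict"),
                            damage_window = 25L, min_overlap = 10000L,
                            phylo = NULL, read_params = read_filter_params(),
                            out_dir = NULL, seed = 1L) {
  if (is.character(reference)) reference <- read_reference(reference)
  stopifnot(inherits(reference, "mito_reference"))
  if (!length(samples)) stop("empty sample list")
  if (is.null(names(samples)) || any(names(samples) == ""))
    stop("samples must be a named list")
  allowed <- c("reads", "fastq", "sam", "library_type")
  for (nm in names(samples)) {
    s <- samples[[nm]]
    bad <- setdiff(names(s), allowed)
    if (length(bad))
      stop("unknown sample field(s) for ", nm, ": ",
           paste(bad, collapse = ", "))
    src <- c("reads", "fastq", "sam") %in% names(s)
    if (sum(src) != 1L)
      stop("sample ", nm, " needs exactly one of reads/fastq/sam")
    for (fld in c("fastq", "sam"))
      if (!is.null(s[[fld]]) && !file.exists(s[[fld]]))
        stop("sample ", nm, ": missing file ", s[[fld]])
    samples[[nm]]$library_type <- s$library_type %||% "single_stranded"
  }
  stopifnot(all(tiers %in% c("relaxed", "strict")), length(tiers) >= 1)
  if (!is.null(phylo)) stopifnot(inherits(phylo, "phylo_params"))
  structure(list(reference = reference, samples = samples, tiers = tiers,
                 damage_window = as.integer(damage_window),
                 min_overlap = as.integer(min_overlap), phylo = phylo,
                 read_params = read_params, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

process_sample <- function(nm, s, ref, cfg) {
  reads <- if (!is.null(s$reads)) s$reads
  else if (!is.null(s$fastq)) read_fastq(s$fastq, sample_id = nm)
  else NULL
  if (!is.null(reads)) {
    reads <- reads[nchar(reads$seq) >= cfg$read_params$min_len, ,
                   drop = FALSE]
    alns <- map_reads(reads, ref)
  } else {
    alns <- read_sam(s$sam, sample_id = nm)
    alns <- alns[order(alns$start, alns$end, alns$strand), , drop = FALSE]
  }
  alns <- filter_mapq(alns, cfg$read_params)
  alns <- dedup(alns)
  if (nrow(alns) == 0L) stop("pipeline stage 'mapping': no usable reads ",
                             "for sample ", nm)
  profile <- estimate_damage(alns, ref, window = cfg$damage_window,
                             library_type = s$library_type)
  if (!profile$flagged && !is.na(profile$fitted_d0) &&
      profile$fitted_d0 > 0)
    alns <- rescale_quals(alns, profile, ref)
  p <- pileup(alns, ref)
  calls <- call_sites(p, ref)
  list(alignments = alns, profile = profile, pileup = p, calls = calls,
       coverage = p$coverage)
}

#' Run the full identity-matching pipeline
#'
#' Per sample: length filter, circular mapping (or SAM ingestion), MAPQ
#' filter, duplicate removal, damage-profile estimation and quality
#' rescaling, pileup, haploid genotype calling, and consensus building
#' under each requested tier. Globally, per tier: sample inclusion by
#' missingness, reference-projected alignment, complete-deletion pairwise
#' difference matrix, identity-match report, and (when `phylo` params are
#' supplied) an NJ+HKY bootstrap tree from the relaxed alignment.
#' Identical config and seed give identical outputs.
#'
#' @param cfg a [pipeline_config()].
#' @return report bundle (class `pipeline_report`): per-sample results,
#'   per-tier consensuses/inclusion/distance matrices/match reports, the
#'   optional tree, and a run log.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  ref <- cfg$reference
  log <- c(sprintf("aukmatch run, seed %d, reference %s (%d bp)",
                   cfg$seed, ref$id, length(ref)),
           sprintf("samples: %s", paste(names(cfg$samples), collapse = ", ")),
           sprintf("tiers: %s; damage window %d; min_overlap %d",
                   paste(cfg$tiers, collapse = "+"), cfg$damage_window,
                   cfg$min_overlap))
  per_sample <- lapply(names(cfg$samples), function(nm)
    process_sample(nm, cfg$samples[[nm]], ref, cfg))
  names(per_sample) <- names(cfg$samples)
  for (nm in names(per_sample))
    log <- c(log, sprintf("  %s: coverage %.2f, fitted d0 %.4f", nm,
                          per_sample[[nm]]$coverage,
                          per_sample[[nm]]$profile$fitted_d0))

  per_tier <- list()
  for (tn in cfg$tiers) {
    tier <- filter_tier(tn)
    cons <- lapply(names(per_sample), function(nm)
      apply_tier(per_sample[[nm]]$calls, tier, sample_id = nm))
    names(cons) <- names(per_sample)
    incl <- lapply(cons, include_sample, tier = tier)
    keep <- vapply(incl, `[[`, logical(1), "included")
    log <- c(log, vapply(incl, `[[`, character(1), "reason"))
    tier_res <- list(consensuses = cons, inclusion = incl)
    if (sum(keep) >= 2L) {
      msa <- build_alignment(cons[keep])
      dm <- pairwise_diffs(msa, mode = "complete")
      mr <- match_candidates(dm, min_overlap = cfg$min_overlap)
      tier_res$alignment <- msa
      tier_res$distance <- dm
      tier_res$matches <- mr
      log <- c(log, sprintf("  [%s] %d columns after complete deletion; %d matched pair(s)",
                            tn, dm$positions_used, nrow(mr$matched)))
    }
    per_tier[[tn]] <- tier_res
  }

  tree <- NULL
  tree_tier <- if ("relaxed" %in% cfg$tiers) "relaxed" else cfg$tiers[1]
  if (!is.null(cfg$phylo) && !is.null(per_tier[[tree_tier]]$alignment) &&
      length(per_tier[[tree_tier]]$alignment$sample_ids) >= 3L) {
    msa_cd <- complete_deletion(per_tier[[tree_tier]]$alignment)
    if (cfg$phylo$n_bootstrap >= 1L) {
      tree <- bootstrap_support(msa_cd, cfg$phylo)
    } else {
      dm <- per_tier[[tree_tier]]$distance
      tree <- optimize_branches(nj_tree(dm), msa_cd, cfg$phylo)
    }
    log <- c(log, sprintf("tree built from %s alignment (%d columns)",
                          tree_tier, msa_cd$n_columns))
  }

  report <- structure(list(samples = per_sample, tiers = per_tier,
                           tree = tree, log = log, config = cfg),
                      class = "pipeline_report")
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- report$config
  ref <- cfg$reference
  manifest <- character(0)
  emit <- function(path) {
    manifest <<- c(manifest,
                   sprintf("%s\t%s", path,
                           unname(tools::md5sum(path))))
  }
  for (nm in names(report$samples)) {
    rs <- report$samples[[nm]]
    vp <- file.path(out_dir, paste0(nm, ".vcf"))
    write_vcf(rs$calls, ref, nm, vp); emit(vp)
    dp <- file.path(out_dir, paste0(nm, ".damage.tsv"))
    write_damage_profile(rs$profile, dp,
                         file.path(out_dir, paste0(nm, ".damage.json")))
    emit(dp)
  }
  for (tn in names(report$tiers)) {
    tr <- report$tiers[[tn]]
    fp <- file.path(out_dir, paste0("consensus_", tn, ".fasta"))
    write_consensus_fasta(tr$consensuses, fp); emit(fp)
    if (!is.null(tr$distance)) {
      mp <- file.path(out_dir, paste0("distance_", tn, ".tsv"))
      write_distance_matrix(tr$distance, mp); emit(mp)
      rp <- file.path(out_dir, paste0("matches_", tn, ".tsv"))
      write.table(tr$matches$pairs, rp, sep = "\t", quote = FALSE,
                  row.names = FALSE); emit(rp)
    }
  }
  if (!is.null(report$tree)) {
    tp <- file.path(out_dir, "tree.nwk")
    write_tree(report$tree, tp); emit(tp)
  }
  lp <- file.path(out_dir, "run.log")
  writeLines(c(report$log, "", "manifest:", manifest), lp)
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(paste(x$log, collapse = "\n"), "\n")
  invisible(x)
}

#' Published study tables shipped with the package
#'
#' `auk_pairwise_table()` returns the published 7-sample pairwise
#' base-difference matrix (relaxed consensus, complete deletion over
#' 15,790 positions) as a `distance_matrix`; `auk_sample_table()` returns
#' the per-sample read-processing summary (coverage, consensus lengths,
#' library type) used to parameterise realistic simulations.
#'
#' @return see description.
#' @export
auk_pairwise_table <- function() {
  path <- system.file("extdata", "great_auk_pairwise_diffs.tsv",
                      package = "aukmatch", mustWork = TRUE)
  ingest_matrix(path, positions_used = 15790L)
}

#' @rdname auk_pairwise_table
#' @export
auk_sample_table <- function() {
  path <- system.file("extdata", "great_auk_samples.tsv",
                      package = "aukmatch", mustWork = TRUE)
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
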