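## NQS-based SNP discovery. A variant base is trusted only when it has high
## PHRED quality itself, sits in a cleanly aligned high-quality neighbourhood
## (the neighbourhood quality standard), and the site passes depth and
## allele-support filters.

#' Caller configuration
#'
#' Default thresholds: variant base PHRED >= 23; the 5 bases on each side
#' aligned exactly with PHRED > 15; at most 1 mismatch within 10 flanking
#' bases; reads with more than 30 mismatches dropped; sites with more than
#' 100 aligned reads dropped; at coverage below 0.1x the mismatch and depth
#' caps are scaled down; with passing depth greater than 3 the minor allele
#' needs at least 2 supporting reads; more than 2 alleles per individual
#' discards the site.
#'
#' @param min_variant_phred minimum PHRED at the variant base (inclusive).
#' @param min_flank_phred flanking bases must exceed this PHRED (exclusive).
#' @param exact_flank_bp bases on each side that must align exactly.
#' @param mismatch_window_bp one-sided width of the mismatch-count window.
#' @param max_flank_mismatches maximum mismatches allowed in that window.
#' @param max_read_mismatches reads above this mismatch count are dropped.
#' @param max_site_depth sites with more aligned reads are dropped.
#' @param low_coverage_threshold genome coverage (x) below which caps shrink.
#' @param low_coverage_scale factor applied to max_read_mismatches and
#'   max_site_depth under low coverage.
#' @param min_minor_reads minor-allele read support required at covered sites.
#' @param min_depth_for_minor_rule passing depth at which the minor-allele
#'   rule engages (4 = "coverage of greater than 3").
#' @param max_alleles_per_individual allele cap per individual per site.
#' @return list of class \code{caller_config}.
#' @export
caller_config <- function(min_variant_phred = 23L, min_flank_phred = 15L,
                          exact_flank_bp = 5L, mismatch_window_bp = 10L,
                          max_flank_mismatches = 1L, max_read_mismatches = 30L,
                          max_site_depth = 100L, low_coverage_threshold = 0.1,
                          low_coverage_scale = 0.5, min_minor_reads = 2L,
                          min_depth_for_minor_rule = 4L,
                          max_alleles_per_individual = 2L) {
  cfg <- list(min_variant_phred = min_variant_phred,
              min_flank_phred = min_flank_phred,
              exact_flank_bp = exact_flank_bp,
              mismatch_window_bp = mismatch_window_bp,
              max_flank_mismatches = max_flank_mismatches,
              max_read_mismatches = max_read_mismatches,
              max_site_depth = max_site_depth,
              low_coverage_threshold = low_coverage_threshold,
              low_coverage_scale = low_coverage_scale,
              min_minor_reads = min_minor_reads,
              min_depth_for_minor_rule = min_depth_for_minor_rule,
              max_alleles_per_individual = max_alleles_per_individual)
  num <- unlist(cfg)
  if (any(num <= 0)) stop("all caller thresholds must be positive")
  if (cfg$exact_flank_bp > cfg$mismatch_window_bp)
    stop("exact_flank_bp must not exceed mismatch_window_bp")
  structure(cfg, class = "caller_config")
}

## Depth/mismatch caps effective at the given genome coverage.
effective_caps <- function(cfg, genome_coverage) {
  s <- if (genome_coverage < cfg$low_coverage_threshold) cfg$low_coverage_scale else 1
  list(max_read_mismatches = floor(cfg$max_read_mismatches * s),
       max_site_depth = floor(cfg$max_site_depth * s))
}

#' Neighbourhood quality standard test for one read base
#'
#' A base passes when (a) its own PHRED quality is at least
#' \code{min_variant_phred}; (b) each of the \code{exact_flank_bp} bases on
#' both sides exists in the read, aligns gaplessly as a match to the
#' reference, and has PHRED above \code{min_flank_phred}; and (c) at most
#' \code{max_flank_mismatches} mismatches occur within
#' \code{mismatch_window_bp} bases on either side (the window truncates at
#' read ends; the variant base itself is not counted).
#'
#' @param read one row of an \code{aligned_reads} table.
#' @param read_offset 0-based index of the base on the read.
#' @param cfg a \code{caller_config}.
#' @param genome a \code{reference_genome} (used unless \code{aln} given).
#' @param aln optional precomputed \code{\link{alignment_columns}} result.
#' @return TRUE/FALSE. Insufficient flank (too near a read end) is FALSE,
#'   not an error.
#' @export
nqs_pass <- function(read, read_offset, cfg = caller_config(), genome = NULL,
                     aln = NULL) {
  if (is.null(aln)) aln <- alignment_columns(read, genome)
  rp <- read_offset + 1L
  i <- match(rp, aln$read_pos)
  if (is.na(i)) return(FALSE)  # clipped/inserted base: not an aligned column
  if (aln$qual[i] < cfg$min_variant_phred) return(FALSE)
  for (k in seq_len(cfg$exact_flank_bp)) {
    for (side in c(-1L, 1L)) {
      j <- match(rp + side * k, aln$read_pos)
      if (is.na(j)) return(FALSE)                       # off read end or unaligned
      if (aln$ref_pos[j] != aln$ref_pos[i] + side * k) return(FALSE)  # gapped
      if (aln$mismatch[j]) return(FALSE)
      if (aln$qual[j] <= cfg$min_flank_phred) return(FALSE)
    }
  }
  win <- aln$read_pos >= rp - cfg$mismatch_window_bp &
         aln$read_pos <= rp + cfg$mismatch_window_bp &
         aln$read_pos != rp
  sum(aln$mismatch[win]) <= cfg$max_flank_mismatches
}

empty_snp_calls <- function() {
  df <- data.frame(seq_name = character(0), pos = integer(0),
                   ref_allele = character(0), individual = character(0),
                   sara = logical(0), stringsAsFactors = FALSE)
  df$alt_alleles <- list()
  df$counts <- list()
  class(df) <- c("snp_calls", "data.frame")
  df
}

snp_call_row <- function(seq_name, pos, ref, alts, individual, counts, sara) {
  df <- data.frame(seq_name = seq_name, pos = as.integer(pos),
                   ref_allele = ref, individual = individual, sara = sara,
                   stringsAsFactors = FALSE)
  df$alt_alleles <- list(alts)
  df$counts <- list(counts)
  df
}

## Per-individual site evidence shared by call_snps and sara_genotype.
## Returns, per candidate ref position, the NQS-passing read bases.
site_evidence <- function(reads, genome, cfg, caps, positions = NULL) {
  keep <- reads$mate_status != "improperly_paired"
  reads <- reads[keep, , drop = FALSE]
  if (nrow(reads) == 0L) return(list())
  alns <- lapply(seq_len(nrow(reads)), function(i)
    alignment_columns(reads[i, ], genome))
  n_mm <- vapply(alns, function(a) sum(a$mismatch), 1L)
  ok <- n_mm <= caps$max_read_mismatches
  reads <- reads[ok, , drop = FALSE]; alns <- alns[ok]
  if (nrow(reads) == 0L) return(list())
  if (is.null(positions)) {
    positions <- sort(unique(unlist(lapply(alns, function(a)
      a$ref_pos[a$mismatch]))))
  }
  out <- list()
  for (p in positions) {
    covering <- which(vapply(alns, function(a) p %in% a$ref_pos, TRUE))
    depth <- length(covering)
    if (depth == 0L) next
    if (depth > caps$max_site_depth) {
      out[[as.character(p)]] <- list(pos = p, depth = depth,
                                     bases = character(0), over_depth = TRUE)
      next
    }
    bases <- character(0)
    for (ri in covering) {
      a <- alns[[ri]]
      j <- match(p, a$ref_pos)
      if (nqs_pass(reads[ri, ], a$read_pos[j] - 1L, cfg, aln = a))
        bases <- c(bases, a$read_base[j])
    }
    out[[as.character(p)]] <- list(pos = p, depth = depth, bases = bases,
                                   over_depth = FALSE)
  }
  out
}

#' Call SNPs from aligned reads
#'
#' Per individual: reads that are improperly paired or carry more than
#' \code{max_read_mismatches} mismatches are dropped; candidate sites with
#' aligned-read depth above \code{max_site_depth} are dropped; remaining
#' mismatch columns are filtered by \code{\link{nqs_pass}}; sites where one
#' individual shows more than two distinct passing alleles are discarded;
#' and when the passing depth reaches \code{min_depth_for_minor_rule} the
#' minor allele must be seen on at least \code{min_minor_reads} reads. The
#' mismatch and depth caps shrink by \code{low_coverage_scale} when
#' \code{genome_coverage} is below \code{low_coverage_threshold}.
#'
#' @param reads an \code{aligned_reads} table.
#' @param genome a \code{reference_genome}.
#' @param cfg a \code{caller_config}.
#' @param genome_coverage estimated genome coverage (x).
#' @return data.frame of class \code{snp_calls}, sorted by (seq, pos,
#'   individual), with per-allele supporting-read counts.
#' @export
call_snps <- function(reads, genome, cfg = caller_config(), genome_coverage = 1) {
  unknown <- setdiff(unique(reads$seq_name), names(genome$sequences))
  if (length(unknown) > 0L)
    stop_coord("reads reference unknown sequence(s): ",
               paste(unknown, collapse = ", "))
  caps <- effective_caps(cfg, genome_coverage)
  calls <- list()
  for (ind in sort(unique(reads$individual))) {
    for (sq in sort(unique(reads$seq_name[reads$individual == ind]))) {
      r <- reads[reads$individual == ind & reads$seq_name == sq, , drop = FALSE]
      ev <- site_evidence(r, genome, cfg, caps)
      for (e in ev) {
        if (e$over_depth || length(e$bases) == 0L) next
        ref <- ref_seq(genome, sq, e$pos)
        tab <- table(e$bases)
        if (length(tab) > cfg$max_alleles_per_individual) next
        alts <- setdiff(names(tab), ref)
        if (length(alts) == 0L) next
        if (sum(tab) >= cfg$min_depth_for_minor_rule && length(tab) >= 2L &&
            min(tab) < cfg$min_minor_reads) next
        calls[[length(calls) + 1L]] <- snp_call_row(
          sq, e$pos, ref, alts, ind,
          stats::setNames(as.integer(tab), names(tab)), sara = FALSE)
      }
    }
  }
  if (length(calls) == 0L) return(empty_snp_calls())
  out <- do.call(rbind, calls)
  out <- out[order(out$seq_name, out$pos, out$individual), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("snp_calls", "data.frame")
  out
}

#' SARA genotyping at known variant loci
#'
#' For each known SNV locus and individual, if all NQS-passing observations
#' equal the reference allele (with the same read, depth and allele-count
#' filters as \code{\link{call_snps}}), a "Same As Reference Assembly" call
#' is emitted: a computational assay asserting the individual carries only
#' the reference allele there. Loci with any passing non-reference
#' observation are left to \code{\link{call_snps}}; loci with no passing
#' observation yield nothing.
#'
#' @param reads an \code{aligned_reads} table.
#' @param known_variants a \code{variant_records} table of known loci (only
#'   single-base records are assayed).
#' @param genome a \code{reference_genome}.
#' @param cfg a \code{caller_config}.
#' @param genome_coverage estimated genome coverage (x).
#' @return \code{snp_calls} with \code{sara = TRUE}.
#' @export
sara_genotype <- function(reads, known_variants, genome, cfg = caller_config(),
                          genome_coverage = 1) {
  caps <- effective_caps(cfg, genome_coverage)
  kv <- known_variants[known_variants$start == known_variants$end, , drop = FALSE]
  calls <- list()
  for (ind in sort(unique(reads$individual))) {
    for (sq in sort(unique(kv$seq_name))) {
      pos <- kv$start[kv$seq_name == sq]
      r <- reads[reads$individual == ind & reads$seq_name == sq, , drop = FALSE]
      if (nrow(r) == 0L) next
      ev <- site_evidence(r, genome, cfg, caps, positions = pos)
      for (e in ev) {
        if (e$over_depth || length(e$bases) == 0L) next
        ref <- ref_seq(genome, sq, e$pos)
        if (any(e$bases != ref)) next   # alternative allele observed
        calls[[length(calls) + 1L]] <- snp_call_row(
          sq, e$pos, ref, character(0), ind,
          stats::setNames(length(e$bases), ref), sara = TRUE)
      }
    }
  }
  if (length(calls) == 0L) return(empty_snp_calls())
  out <- do.call(rbind, calls)
  out <- out[order(out$seq_name, out$pos, out$individual), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("snp_calls", "data.frame")
  out
}

#' Convert SNP calls to variant records
#'
#' Read counts and the individual go into the INFO column
#' (\code{IND=...;RC=base:count,...}; SARA calls additionally carry
#' \code{SARA}).
#'
#' @param calls a \code{snp_calls} table.
#' @param id_prefix prefix for generated identifiers.
#' @return a \code{variant_records} table with an \code{info} column.
#' @export
calls_to_variant_records <- function(calls, id_prefix = "VKSNP") {
  if (nrow(calls) == 0L)
    return(variant_records(character(0), integer(0), integer(0),
                           character(0), list()))
  real <- calls[!calls$sara, , drop = FALSE]
  if (nrow(real) == 0L)
    return(variant_records(character(0), integer(0), integer(0),
                           character(0), list()))
  v <- variant_records(
    seq_name = real$seq_name, start = real$pos, end = real$pos,
    ref_allele = real$ref_allele, alt_alleles = real$alt_alleles,
    id = sprintf("%s%06d", id_prefix, seq_len(nrow(real))),
    source = "variantkit")
  v$info <- vapply(seq_len(nrow(real)), function(i) {
    rc <- real$counts[[i]]
    paste0("IND=", real$individual[i], ";RC=",
           paste(names(rc), rc, sep = ":", collapse = ","))
  }, "")
  v
}
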