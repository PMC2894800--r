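## Transcript consequence annotation: assign every (variant, transcript)
## pair a consequence type from a closed, severity-ranked vocabulary, with
## coding-level detail (codons, amino acids, positions) where the variant
## touches the peptide.

#' The consequence vocabulary, in estimated order of importance
#'
#' Rank 1 is the most severe. Splice-site positional rules: the first or
#' last 2 bases of an intron are the essential splice site, 3-8 bp into an
#' intron the extended splice region, and 1-3 bp into an exon add a splice
#' modifier to the exonic class. Up/downstream extends 5 kb from the
#' transcript; beyond that a variant is intergenic.
#'
#' @return character vector; position = severity rank.
#' @export
consequence_types <- function() {
  c("Stop gained",
    "Stop lost",
    "Complex InDel",
    "Frameshift coding",
    "Stop gained, frameshift coding",
    "Non-synonymous coding",
    "Stop gained, splice site",
    "Stop lost, splice site",
    "Frameshift coding, splice site",
    "Stop gained, frameshift coding, splice site",
    "Non-synonymous coding, splice site",
    "Synonymous coding",
    "Splice site, synonymous coding",
    "Regulatory region",
    "Within mature miRNA",
    "5' UTR",
    "Splice site, 5' UTR",
    "3' UTR",
    "Splice site, 3' UTR",
    "Intronic",
    "Essential splice site, intronic",
    "Splice site, intronic",
    "Upstream",
    "Downstream",
    "Within non-coding gene",
    "Intergenic")
}

#' @rdname consequence_types
#' @param type consequence label(s).
#' @return integer severity rank(s) (1 = most severe).
#' @export
consequence_rank <- function(type) {
  r <- match(type, consequence_types())
  if (anyNA(r)) stop("unknown consequence type: ",
                     paste(type[is.na(r)], collapse = ", "))
  r
}

consequence_call <- function(variant_id, transcript_id, type, allele = NA,
                             cdna_pos = NA, cds_pos = NA, protein_pos = NA,
                             ref_codon = NA, alt_codon = NA,
                             ref_aa = NA, alt_aa = NA) {
  data.frame(variant_id = variant_id, transcript_id = transcript_id,
             consequence_type = type, rank = consequence_rank(type),
             allele = allele, cdna_pos = as.integer(cdna_pos),
             cds_pos = as.integer(cds_pos),
             protein_pos = as.integer(protein_pos),
             ref_codon = ref_codon, alt_codon = alt_codon,
             ref_aa = ref_aa, alt_aa = alt_aa, stringsAsFactors = FALSE)
}

#' Transcripts and regulatory features in scope for a variant
#'
#' A transcript is in scope when the variant lies within its span extended
#' by \code{flank} bp (default 5 kb) on both sides; regulatory features are
#' in scope when overlapped. An empty result means the variant is
#' intergenic.
#'
#' @param seq_name,start,end the variant's mapping.
#' @param transcripts list of \code{transcript_model}s.
#' @param regulatory optional \code{regulatory_features}.
#' @param flank scope distance in bp.
#' @return list with elements \code{transcripts} (sublist) and
#'   \code{regulatory} (data.frame subset).
#' @export
transcripts_in_scope <- function(seq_name, start, end, transcripts,
                                 regulatory = NULL, flank = 5000L) {
  lo <- min(start, end); hi <- max(start, end)
  keep <- vapply(transcripts, function(t)
    t$seq_name == seq_name && hi >= tx_start(t) - flank && lo <= tx_end(t) + flank,
    TRUE)
  regs <- if (is.null(regulatory)) NULL else
    regulatory[regulatory$seq_name == seq_name &
               hi >= regulatory$start & lo <= regulatory$end, , drop = FALSE]
  list(transcripts = transcripts[keep], regulatory = regs)
}

## Region of an exonic genomic base on a coding transcript:
## "5' UTR", "CDS" or "3' UTR". pos must be exonic.
exonic_region <- function(t, pos) {
  cdna <- genomic_to_cdna(t, pos)
  b <- cds_cdna_bounds(t)
  if (cdna < b[1L]) "5' UTR" else if (cdna > b[2L]) "3' UTR" else "CDS"
}

## Classify a single alt allele against one transcript. Returns a one-row
## consequence data.frame or NULL when out of the 5 kb scope.
classify_allele <- function(variant_id, v_start, v_end, ref, alt, t, genome,
                            flank = 5000L) {
  lo <- min(v_start, v_end); hi <- max(v_start, v_end)
  ## outside the transcript span: up/downstream by transcript orientation
  if (hi < tx_start(t) || lo > tx_end(t)) {
    dist <- if (hi < tx_start(t)) tx_start(t) - hi else lo - tx_end(t)
    if (dist > flank) return(NULL)
    left_of_tx <- hi < tx_start(t)
    type <- if ((left_of_tx && t$strand > 0L) || (!left_of_tx && t$strand < 0L))
      "Upstream" else "Downstream"
    return(consequence_call(variant_id, t$id, type, allele = alt))
  }
  ## non-coding transcript
  if (!is_coding(t)) {
    in_mirna <- !is.null(t$mature_mirna) &&
      any(hi >= t$mature_mirna[, "start"] & lo <= t$mature_mirna[, "end"])
    return(consequence_call(variant_id, t$id,
                            if (in_mirna) "Within mature miRNA"
                            else "Within non-coding gene", allele = alt))
  }
  is_insertion <- v_start == v_end + 1L
  affected <- if (is_insertion) c(v_end, v_start) else v_start:v_end
  affected <- affected[affected >= tx_start(t) & affected <= tx_end(t)]
  ios <- lapply(affected, function(p) intron_offset(t, p))
  intronic <- !vapply(ios, is.null, TRUE)
  exonic <- !intronic
  ref_len <- if (ref == "-") 0L else nchar(ref)
  alt_len <- if (alt == "-") 0L else nchar(alt)
  is_snv <- ref_len == 1L && alt_len == 1L && v_start == v_end
  is_indel <- ref_len != alt_len

  ## splice modifier: any affected exonic base 1-3 bp into an exon
  eos <- vapply(affected[exonic], function(p) {
    e <- exon_edge_offset(t, p); if (is.null(e)) NA_integer_ else e
  }, 1L)
  splice_mod <- any(!is.na(eos) & eos <= 3L)

  if (all(intronic)) {
    ## an insertion between two intronic bases, or an intronic (del/snv) span
    d <- min(vapply(ios[intronic], `[[`, 1L, "offset"))
    type <- if (d <= 2L) "Essential splice site, intronic"
            else if (d <= 8L) "Splice site, intronic" else "Intronic"
    return(consequence_call(variant_id, t$id, type, allele = alt))
  }
  if (any(intronic) && any(exonic)) {
    ## spanning an exon/intron border
    if (is_indel || !is_snv)
      return(consequence_call(variant_id, t$id, "Complex InDel", allele = alt))
  }
  ## fully exonic (for insertions: both flanking bases exonic)
  regions <- vapply(affected[exonic], function(p) exonic_region(t, p), "")
  if (is_insertion) {
    ## region of the insertion point: between the two flanking bases
    regions <- unique(regions)
    if (length(regions) > 1L) regions <- "CDS"  # at a CDS/UTR junction: coding side
  }
  if (length(unique(regions)) > 1L) {
    if (is_indel)
      return(consequence_call(variant_id, t$id, "Complex InDel", allele = alt))
    regions <- "CDS"  # multi-base substitution straddling a border: coding wins
  }
  region <- unique(regions)

  if (region != "CDS") {
    base <- if (region == "5' UTR") "5' UTR" else "3' UTR"
    type <- if (splice_mod) paste0("Splice site, ", base) else base
    cdna <- genomic_to_cdna(t, affected[1L])
    return(consequence_call(variant_id, t$id, type, allele = alt,
                            cdna_pos = cdna))
  }

  ## CDS
  if (is_indel) {
    shift <- (alt_len - ref_len) %% 3L
    type <- if (shift != 0L) {
      if (splice_mod) "Frameshift coding, splice site" else "Frameshift coding"
    } else {
      ## in-frame indel wholly inside the CDS: closest coding-change label
      if (splice_mod) "Non-synonymous coding, splice site" else "Non-synonymous coding"
    }
    cp <- genomic_to_cds(t, affected[1L]) %||% genomic_to_cds(t, affected[length(affected)])
    return(consequence_call(variant_id, t$id, type, allele = alt,
                            cdna_pos = genomic_to_cdna(t, affected[1L]),
                            cds_pos = if (is.list(cp)) cp$cds_pos else NA,
                            protein_pos = if (is.list(cp)) cp$codon_index else NA))
  }
  if (!is_snv) {
    ## same-length multi-base substitution in CDS: coding change
    type <- if (splice_mod) "Non-synonymous coding, splice site" else "Non-synonymous coding"
    cp <- genomic_to_cds(t, affected[1L])
    return(consequence_call(variant_id, t$id, type, allele = alt,
                            cdna_pos = genomic_to_cdna(t, affected[1L]),
                            cds_pos = cp$cds_pos, protein_pos = cp$codon_index))
  }

  ## CDS SNV: translate reference and alternate codons
  pos <- v_start
  cp <- genomic_to_cds(t, pos)
  cds <- cds_sequence(t, genome)
  codon_start <- 3L * (cp$codon_index - 1L) + 1L
  ref_codon <- substr(cds, codon_start, min(codon_start + 2L, nchar(cds)))
  alt_t <- if (t$strand < 0L) revcomp(alt) else alt
  alt_codon <- ref_codon
  substr(alt_codon, cp$codon_offset + 1L, cp$codon_offset + 1L) <- alt_t
  ref_aa <- translate_dna(ref_codon)
  alt_aa <- translate_dna(alt_codon)
  base_type <-
    if (nchar(ref_codon) < 3L) "Synonymous coding"  # incomplete terminal codon
    else if (alt_aa == "*" && ref_aa != "*") "Stop gained"
    else if (ref_aa == "*" && alt_aa != "*") "Stop lost"
    else if (ref_aa == alt_aa) "Synonymous coding"
    else "Non-synonymous coding"
  type <- if (!splice_mod) base_type else switch(
    base_type,
    "Stop gained" = "Stop gained, splice site",
    "Stop lost" = "Stop lost, splice site",
    "Synonymous coding" = "Splice site, synonymous coding",
    "Non-synonymous coding" = "Non-synonymous coding, splice site")
  consequence_call(variant_id, t$id, type, allele = alt,
                   cdna_pos = genomic_to_cdna(t, pos), cds_pos = cp$cds_pos,
                   protein_pos = cp$codon_index, ref_codon = ref_codon,
                   alt_codon = alt_codon, ref_aa = ref_aa, alt_aa = alt_aa)
}

#' Classify one variant against one transcript
#'
#' Emits one consequence per alternate allele; when a multi-allelic variant
#' yields both a stop gain and a frameshift on the same transcript, the two
#' calls are combined into the dedicated multi-allelic class.
#'
#' @param variant_id identifier used in the output.
#' @param v_start,v_end variant mapping (insertions: start = end + 1).
#' @param ref reference allele ("-" for insertions).
#' @param alts character vector of alternate alleles.
#' @param t a \code{transcript_model}.
#' @param genome a \code{reference_genome}.
#' @param flank scope distance (bp).
#' @return data.frame of consequence calls (possibly zero rows).
#' @export
classify_variant <- function(variant_id, v_start, v_end, ref, alts, t, genome,
                             flank = 5000L) {
  calls <- lapply(alts, function(a)
    classify_allele(variant_id, v_start, v_end, ref, a, t, genome, flank))
  calls <- calls[!vapply(calls, is.null, TRUE)]
  if (length(calls) == 0L)
    return(consequence_call("x", "x", "Intergenic")[0L, ])
  df <- do.call(rbind, calls)
  sg <- startsWith(df$consequence_type, "Stop gained") &
        !grepl("frameshift", df$consequence_type)
  fs <- startsWith(df$consequence_type, "Frameshift coding")
  if (any(sg) && any(fs)) {
    spl <- any(grepl("splice site", df$consequence_type[sg | fs]))
    combined <- consequence_call(
      variant_id, t$id,
      if (spl) "Stop gained, frameshift coding, splice site"
      else "Stop gained, frameshift coding",
      allele = paste(df$allele[sg | fs], collapse = "/"))
    df <- rbind(combined, df[!(sg | fs), , drop = FALSE])
  }
  rownames(df) <- NULL
  df
}

#' Sort consequence calls by severity
#'
#' Stable sort by rank (1 = most severe), ties broken by transcript id.
#'
#' @param calls a consequence-call data.frame.
#' @return the sorted data.frame.
#' @export
rank_calls <- function(calls) {
  tid <- ifelse(is.na(calls$transcript_id), "~", calls$transcript_id)
  out <- calls[order(calls$rank, tid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate variants with transcript consequences
#'
#' For each variant record, finds transcripts within 5 kb and overlapping
#' regulatory features, classifies every alternate allele against each, adds
#' a Regulatory region call per overlapped feature, and emits a single
#' Intergenic call when nothing is in scope. Output is severity-ranked per
#' variant.
#'
#' @param variants a \code{variant_records} table (single mapping per row).
#' @param transcripts list of \code{transcript_model}s.
#' @param genome a \code{reference_genome}.
#' @param regulatory optional \code{regulatory_features}.
#' @param flank scope distance in bp.
#' @return data.frame of consequence calls.
#' @export
annotate_variants <- function(variants, transcripts, genome,
                              regulatory = NULL, flank = 5000L) {
  out <- list()
  for (i in seq_len(nrow(variants))) {
    vid <- variants$id[i] %||%
      paste0(variants$seq_name[i], ":", variants$start[i])
    if (is.na(vid)) vid <- paste0(variants$seq_name[i], ":", variants$start[i])
    scope <- transcripts_in_scope(variants$seq_name[i], variants$start[i],
                                  variants$end[i], transcripts, regulatory,
                                  flank)
    calls <- lapply(scope$transcripts, function(t)
      classify_variant(vid, variants$start[i], variants$end[i],
                       variants$ref_allele[i], variants$alt_alleles[[i]],
                       t, genome, flank))
    calls <- calls[vapply(calls, nrow, 1L) > 0L]
    if (!is.null(scope$regulatory) && nrow(scope$regulatory) > 0L) {
      for (r in seq_len(nrow(scope$regulatory)))
        calls[[length(calls) + 1L]] <- consequence_call(
          vid, scope$regulatory$linked_gene[r], "Regulatory region")
    }
    if (length(calls) == 0L) {
      calls <- list(consequence_call(vid, NA_character_, "Intergenic"))
    }
    out[[i]] <- rank_calls(do.call(rbind, calls))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write consequence calls to TSV
#'
#' @param calls a consequence-call data.frame.
#' @param path output file.
#' @export
write_consequences_tsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}
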