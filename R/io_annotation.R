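## Readers for reference/annotation formats: FASTA, GTF, GFF3, BED.

#' Read a reference genome from FASTA
#'
#' Multi-record, wrapped lines, case-insensitive. Record names are taken up
#' to the first whitespace.
#'
#' @param path FASTA file (plain or gzip).
#' @return a \code{reference_genome}.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  reference_genome(seqs)
}

#' Write a reference genome to FASTA
#'
#' @param genome a \code{reference_genome}.
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(genome$sequences)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

## Build transcript_model objects from a per-feature table with columns
## type, start, end, strand, seq, transcript_id, gene_id, biotype.
build_transcripts <- function(feat) {
  out <- list()
  for (tid in unique(feat$transcript_id)) {
    f <- feat[feat$transcript_id == tid, , drop = FALSE]
    ex <- f[f$type == "exon", , drop = FALSE]
    if (nrow(ex) == 0L) next
    cds <- f[f$type == "CDS", , drop = FALSE]
    mir <- f[f$type %in% c("mature_miRNA", "miRNA_mature"), , drop = FALSE]
    biotype <- f$biotype[!is.na(f$biotype)][1]
    if (is.na(biotype %||% NA))
      biotype <- if (nrow(cds) > 0L) "protein_coding"
                 else if (nrow(mir) > 0L) "miRNA" else "non_coding"
    if (identical(biotype, "miRNA") && nrow(mir) == 0L && nrow(cds) == 0L) {
      ## tolerate miRNA transcripts without explicit mature intervals
    }
    out[[tid]] <- transcript_model(
      id = tid,
      gene_id = f$gene_id[!is.na(f$gene_id)][1] %||% tid,
      seq_name = ex$seq[1],
      strand = ex$strand[1],
      exons = cbind(ex$start, ex$end),
      cds_start = if (nrow(cds) > 0L) min(cds$start) else NA,
      cds_end = if (nrow(cds) > 0L) max(cds$end) else NA,
      biotype = biotype,
      mature_mirna = if (nrow(mir) > 0L) cbind(start = mir$start, end = mir$end) else NULL)
  }
  out[order(names(out))]
}

gr_to_feat <- function(gr, transcript_id, gene_id, biotype) {
  data.frame(type = as.character(gr$type),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", -1L, 1L),
             seq = as.character(GenomicRanges::seqnames(gr)),
             transcript_id = transcript_id,
             gene_id = gene_id,
             biotype = biotype,
             stringsAsFactors = FALSE)
}

#' Read transcript models from GTF
#'
#' Builds \code{transcript_model} objects from \code{exon}, \code{CDS} and
#' optional \code{mature_miRNA} features, keyed on the standard
#' \code{transcript_id}/\code{gene_id} attributes. Biotype is taken from
#' \code{transcript_biotype} (or \code{gene_biotype}) when present, otherwise
#' inferred from the presence of CDS features.
#'
#' @param path GTF file.
#' @return named list of \code{transcript_model} objects.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  bt <- if ("transcript_biotype" %in% names(md)) md$transcript_biotype
        else if ("gene_biotype" %in% names(md)) md$gene_biotype
        else NA_character_
  feat <- gr_to_feat(gr, md$transcript_id, md$gene_id, bt)
  feat <- feat[!is.na(feat$transcript_id), , drop = FALSE]
  build_transcripts(feat)
}

#' Read transcript models from GFF3
#'
#' Transcript-level features (\code{mRNA}, \code{transcript}, \code{miRNA})
#' carry \code{ID} and \code{Parent} (gene); \code{exon}/\code{CDS} features
#' point at the transcript through \code{Parent}.
#'
#' @param path GFF3 file.
#' @return named list of \code{transcript_model} objects.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  parent <- vapply(as.list(md$Parent), function(p) if (length(p)) p[[1]] else NA_character_, "")
  id <- as.character(md$ID)
  is_tx <- type %in% c("mRNA", "transcript", "miRNA", "ncRNA")
  tx_gene <- stats::setNames(parent[is_tx], id[is_tx])
  tx_bt <- stats::setNames(
    ifelse(type[is_tx] == "mRNA", "protein_coding",
           ifelse(type[is_tx] == "miRNA", "miRNA", "non_coding")),
    id[is_tx])
  if ("biotype" %in% names(md))
    tx_bt[id[is_tx]] <- ifelse(is.na(md$biotype[is_tx]), tx_bt[id[is_tx]], md$biotype[is_tx])
  keep <- type %in% c("exon", "CDS", "mature_miRNA")
  feat <- gr_to_feat(gr[keep], parent[keep],
                     unname(tx_gene[parent[keep]]),
                     unname(tx_bt[parent[keep]]))
  feat <- feat[!is.na(feat$transcript_id), , drop = FALSE]
  build_transcripts(feat)
}

#' Read regulatory features from BED
#'
#' BED3 plus an optional fourth column naming the linked gene. BED intervals
#' are 0-based half-open and are converted to 1-based closed coordinates.
#'
#' @param path BED file.
#' @return a \code{regulatory_features} data.frame.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("seq", "start", "end", "name")[
                            seq_len(max(3L, ncol(utils::read.table(path, sep = "\t", nrows = 1L))))])
  regulatory_features(df$seq, df$start + 1L, df$end,
                      if ("name" %in% names(df)) df$name else NA_character_)
}
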