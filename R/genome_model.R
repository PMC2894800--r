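## Reference sequence and transcript structure: the coordinate frame for the
## consequence engine. All genomic coordinates are 1-based, fully closed, on
## the forward strand; insertions are represented as start = end + 1.

#' Construct a reference genome
#'
#' A reference genome is a named set of nucleotide sequences (A/C/G/T/N,
#' case-insensitive) indexed by sequence name.
#'
#' @param sequences named character vector, one nucleotide string per
#'   sequence (chromosome/contig).
#' @return an object of class \code{reference_genome} with elements
#'   \code{sequences} and \code{lengths}.
#' @export
reference_genome <- function(sequences) {
  if (is.null(names(sequences)) || any(names(sequences) == ""))
    stop("all sequences must be named")
  sequences <- toupper(unlist(sequences))
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    stop("sequence(s) contain characters outside A/C/G/T/N: ",
         paste(names(sequences)[bad], collapse = ", "))
  structure(list(sequences = sequences, lengths = nchar(sequences)),
            class = "reference_genome")
}

#' @export
print.reference_genome <- function(x, ...) {
  cat("reference_genome:", length(x$sequences), "sequence(s)\n")
  for (nm in names(x$sequences))
    cat("  ", nm, ": ", x$lengths[[nm]], " bp\n", sep = "")
  invisible(x)
}

#' Extract reference bases
#'
#' @param genome a \code{reference_genome}.
#' @param seq_name sequence name.
#' @param start,end 1-based closed interval. \code{start = end + 1} (an
#'   insertion point) returns the empty string.
#' @return the reference substring.
#' @export
ref_seq <- function(genome, seq_name, start, end = start) {
  if (!seq_name %in% names(genome$sequences))
    stop_coord("unknown sequence name '", seq_name, "'")
  if (start == end + 1L) return("")
  if (start < 1L || end > genome$lengths[[seq_name]] || start > end)
    stop_coord("interval [", start, ",", end, "] outside sequence '",
               seq_name, "' (length ", genome$lengths[[seq_name]], ")")
  substr(genome$sequences[[seq_name]], start, end)
}

#' Construct a transcript model
#'
#' Strand-aware exon/CDS structure on a reference sequence. Exons are given
#' in genomic coordinates (ascending, non-overlapping); the CDS, when
#' present, must lie within the exon union with spliced length >= 3.
#'
#' @param id transcript identifier.
#' @param gene_id gene identifier.
#' @param seq_name sequence the transcript lies on.
#' @param strand +1 or -1.
#' @param exons two-column matrix or data.frame of genomic (start, end).
#' @param cds_start,cds_end genomic bounds of the CDS, or NA (non-coding).
#' @param biotype one of "protein_coding", "non_coding", "miRNA".
#' @param mature_mirna optional two-column matrix of mature-miRNA
#'   sub-intervals (genomic coordinates).
#' @return an object of class \code{transcript_model}.
#' @export
transcript_model <- function(id, gene_id, seq_name, strand, exons,
                             cds_start = NA, cds_end = NA,
                             biotype = c("protein_coding", "non_coding", "miRNA"),
                             mature_mirna = NULL) {
  biotype <- match.arg(biotype)
  exons <- as.matrix(exons)
  colnames(exons) <- c("start", "end")
  storage.mode(exons) <- "integer"
  exons <- exons[order(exons[, "start"]), , drop = FALSE]
  if (any(exons[, "end"] < exons[, "start"]))
    stop("exon with end < start in transcript ", id)
  if (nrow(exons) > 1L) {
    gap <- exons[-1L, "start"] - exons[-nrow(exons), "end"] - 1L
    if (any(gap < 1L))
      stop("overlapping or abutting exons (intron length < 1) in transcript ", id)
  }
  if (!strand %in% c(1L, -1L)) stop("strand must be +1 or -1")
  if (!is.null(mature_mirna)) {
    mature_mirna <- as.matrix(mature_mirna)
    colnames(mature_mirna) <- c("start", "end")
    storage.mode(mature_mirna) <- "integer"
  }
  t <- structure(list(id = id, gene_id = gene_id, seq_name = seq_name,
                      strand = as.integer(strand), exons = exons,
                      cds_start = as.integer(cds_start),
                      cds_end = as.integer(cds_end),
                      biotype = biotype, mature_mirna = mature_mirna),
                 class = "transcript_model")
  if (is_coding(t)) {
    if (biotype != "protein_coding")
      stop("CDS bounds supplied for non-coding biotype in transcript ", id)
    if (is.null(genomic_to_cdna(t, t$cds_start)) ||
        is.null(genomic_to_cdna(t, t$cds_end)))
      stop("CDS bounds outside exon union in transcript ", id)
    if (cds_length(t) < 3L)
      stop("spliced CDS shorter than one codon in transcript ", id)
  }
  t
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("transcript_model ", x$id, " (", x$gene_id, ") ", x$seq_name, ":",
      tx_start(x), "-", tx_end(x), " strand ", ifelse(x$strand > 0, "+", "-"),
      " [", x$biotype, "], ", nrow(x$exons), " exon(s)",
      if (is_coding(x)) paste0(", CDS ", x$cds_start, "-", x$cds_end) else "",
      "\n", sep = "")
  invisible(x)
}

#' @rdname transcript_model
#' @param t a \code{transcript_model}.
#' @export
is_coding <- function(t) !is.na(t$cds_start) && !is.na(t$cds_end)

#' @rdname transcript_model
#' @export
tx_start <- function(t) t$exons[1L, "start"]

#' @rdname transcript_model
#' @export
tx_end <- function(t) t$exons[nrow(t$exons), "end"]

## Introns as a (start, end) matrix in genomic coordinates; zero rows for a
## single-exon transcript.
tx_introns <- function(t) {
  n <- nrow(t$exons)
  if (n < 2L)
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  cbind(start = t$exons[-n, "end"] + 1L, end = t$exons[-1L, "start"] - 1L)
}

## Genomic positions of the spliced transcript, 5' to 3' in transcript
## orientation.
tx_genomic_positions <- function(t) {
  pos <- unlist(lapply(seq_len(nrow(t$exons)),
                       function(i) t$exons[i, "start"]:t$exons[i, "end"]))
  if (t$strand < 0L) rev(pos) else pos
}

#' Map a genomic position to spliced cDNA coordinate
#'
#' @param t a \code{transcript_model}.
#' @param pos genomic position.
#' @return 1-based position along the spliced transcript (transcript
#'   orientation), or NULL if \code{pos} is not exonic.
#' @export
genomic_to_cdna <- function(t, pos) {
  gp <- tx_genomic_positions(t)
  i <- match(pos, gp)
  if (is.na(i)) NULL else i
}

#' Intron position of a genomic coordinate
#'
#' Distance is measured from the nearest intron edge: the terminal base of an
#' intron has offset 1, so offsets 1-2 are the essential splice dinucleotides
#' and 3-8 the extended splice region. The minimum over both edges is taken,
#' making the value strand-symmetric.
#'
#' @param t a \code{transcript_model}.
#' @param pos genomic position.
#' @param seq_name optional sequence-name check against the transcript.
#' @return \code{list(intron = i, offset = d)} with \code{i} the intron index
#'   in transcript orientation, or NULL if \code{pos} is not intronic.
#' @export
intron_offset <- function(t, pos, seq_name = NULL) {
  if (!is.null(seq_name) && seq_name != t$seq_name)
    stop_coord("position on '", seq_name, "' but transcript ", t$id,
               " lies on '", t$seq_name, "'")
  ints <- tx_introns(t)
  if (nrow(ints) == 0L) return(NULL)
  hit <- which(pos >= ints[, "start"] & pos <= ints[, "end"])
  if (length(hit) == 0L) return(NULL)
  d <- min(pos - ints[hit, "start"] + 1L, ints[hit, "end"] - pos + 1L)
  idx <- if (t$strand < 0L) nrow(ints) - hit + 1L else hit
  list(intron = idx, offset = as.integer(d))
}

#' Distance into an exon from the nearest splice junction
#'
#' Counts from exon boundaries that abut an intron only (transcript termini
#' are not splice junctions): the exonic base adjacent to an intron has
#' offset 1. Returns NULL for non-exonic positions, for single-exon
#' transcripts, and when the position is more than 8 bp from every
#' intron-adjacent boundary.
#'
#' @inheritParams intron_offset
#' @return integer offset (1-8) or NULL.
#' @export
exon_edge_offset <- function(t, pos, seq_name = NULL) {
  if (!is.null(seq_name) && seq_name != t$seq_name)
    stop_coord("position on '", seq_name, "' but transcript ", t$id,
               " lies on '", t$seq_name, "'")
  n <- nrow(t$exons)
  if (n < 2L) return(NULL)
  hit <- which(pos >= t$exons[, "start"] & pos <= t$exons[, "end"])
  if (length(hit) == 0L) return(NULL)
  d <- integer(0)
  if (hit > 1L)  d <- c(d, pos - t$exons[hit, "start"] + 1L)  # left edge abuts intron
  if (hit < n)   d <- c(d, t$exons[hit, "end"] - pos + 1L)    # right edge abuts intron
  if (length(d) == 0L) return(NULL)
  d <- min(d)
  if (d > 8L) NULL else as.integer(d)
}

## cDNA coordinates of the CDS 5' and 3' ends (transcript orientation).
cds_cdna_bounds <- function(t) {
  stopifnot(is_coding(t))
  five <- if (t$strand > 0L) t$cds_start else t$cds_end
  three <- if (t$strand > 0L) t$cds_end else t$cds_start
  c(genomic_to_cdna(t, five), genomic_to_cdna(t, three))
}

#' Spliced CDS length
#' @param t a coding \code{transcript_model}.
#' @export
cds_length <- function(t) {
  b <- cds_cdna_bounds(t)
  b[2L] - b[1L] + 1L
}

#' Map a genomic position into the CDS
#'
#' @inheritParams intron_offset
#' @return \code{list(cds_pos, codon_index, codon_offset)} with
#'   \code{cds_pos} 1-based along the spliced CDS in transcript orientation,
#'   \code{codon_index} 1-based, \code{codon_offset} in 0..2; NULL if
#'   \code{pos} is not a CDS base.
#' @export
genomic_to_cds <- function(t, pos) {
  if (!is_coding(t)) stop("genomic_to_cds called on non-coding transcript ", t$id)
  cdna <- genomic_to_cdna(t, pos)
  if (is.null(cdna)) return(NULL)
  b <- cds_cdna_bounds(t)
  if (cdna < b[1L] || cdna > b[2L]) return(NULL)
  cds_pos <- cdna - b[1L] + 1L
  list(cds_pos = cds_pos,
       codon_index = (cds_pos - 1L) %/% 3L + 1L,
       codon_offset = (cds_pos - 1L) %% 3L)
}

#' Inverse of \code{genomic_to_cds}
#'
#' @param t a coding \code{transcript_model}.
#' @param cds_pos 1-based spliced CDS position.
#' @return the genomic coordinate of that CDS base.
#' @export
cds_to_genomic <- function(t, cds_pos) {
  if (!is_coding(t)) stop("cds_to_genomic called on non-coding transcript ", t$id)
  b <- cds_cdna_bounds(t)
  if (cds_pos < 1L || cds_pos > b[2L] - b[1L] + 1L)
    stop_coord("CDS position ", cds_pos, " outside CDS of ", t$id)
  tx_genomic_positions(t)[b[1L] + cds_pos - 1L]
}

#' Spliced transcript and CDS sequences
#'
#' @param t a \code{transcript_model}.
#' @param genome a \code{reference_genome}.
#' @return nucleotide string in transcript orientation.
#' @export
cdna_sequence <- function(t, genome) {
  s <- paste(vapply(seq_len(nrow(t$exons)), function(i)
    ref_seq(genome, t$seq_name, t$exons[i, "start"], t$exons[i, "end"]), ""),
    collapse = "")
  if (t$strand < 0L) revcomp(s) else s
}

#' @rdname cdna_sequence
#' @export
cds_sequence <- function(t, genome) {
  b <- cds_cdna_bounds(t)
  substr(cdna_sequence(t, genome), b[1L], b[2L])
}

#' Regulatory features
#'
#' @param seq_name,start,end vectors defining genomic intervals.
#' @param linked_gene optional gene ids.
#' @return data.frame of class \code{regulatory_features}.
#' @export
regulatory_features <- function(seq_name, start, end, linked_gene = NA_character_) {
  if (any(end < start)) stop("regulatory feature with end < start")
  structure(data.frame(seq_name = seq_name, start = as.integer(start),
                       end = as.integer(end),
                       linked_gene = linked_gene,
                       stringsAsFactors = FALSE),
            class = c("regulatory_features", "data.frame"))
}
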