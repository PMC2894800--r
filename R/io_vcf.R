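## VCF input/output. Internally, alleles use the browser-style convention:
## SNVs have start == end; deletions span the deleted bases with alt "-";
## insertions have start == end + 1 with ref "-". The VCF anchored-base indel
## style is converted on read and restored on write.

#' Construct a table of variant records
#'
#' @param seq_name,start,end location (1-based closed; insertions have
#'   \code{start == end + 1}).
#' @param ref_allele reference allele ("-" for insertions).
#' @param alt_alleles list of character vectors of alternate alleles
#'   ("-" for deletions).
#' @param id primary identifier.
#' @param synonyms list of character vectors of secondary identifiers.
#' @param source data source label.
#' @param strand strand of report (+1/-1); alleles are as reported.
#' @param anchor VCF anchor base (kept for lossless round trips), or NA.
#' @return data.frame of class \code{variant_records}.
#' @export
variant_records <- function(seq_name, start, end, ref_allele, alt_alleles,
                            id = NA_character_, synonyms = NULL,
                            source = NA_character_, strand = 1L,
                            anchor = NA_character_) {
  n <- max(length(seq_name), length(start), length(alt_alleles))
  if (!is.list(alt_alleles)) alt_alleles <- as.list(alt_alleles)
  if (is.null(synonyms)) synonyms <- rep(list(character(0)), n)
  df <- data.frame(seq_name = rep_len(seq_name, n), start = as.integer(start),
                   end = as.integer(end), ref_allele = ref_allele,
                   id = rep_len(id, n), source = rep_len(source, n),
                   strand = rep_len(as.integer(strand), n),
                   anchor = rep_len(anchor, n), stringsAsFactors = FALSE)
  df$alt_alleles <- alt_alleles
  df$synonyms <- synonyms
  bad <- vapply(seq_len(n), function(i)
    length(df$alt_alleles[[i]]) == 0L || any(df$alt_alleles[[i]] == df$ref_allele[i]),
    TRUE)
  if (any(bad))
    stop("variant(s) with empty alt set or alt equal to ref: row ",
         paste(which(bad), collapse = ", "))
  class(df) <- c("variant_records", "data.frame")
  df
}

## Convert one VCF (pos, ref, alts) to internal coordinates.
vcf_to_internal <- function(pos, ref, alts) {
  if (nchar(ref) == 1L && all(nchar(alts) == 1L))
    return(list(start = pos, end = pos, ref = ref, alts = alts, anchor = NA_character_))
  firsts <- substr(c(ref, alts), 1L, 1L)
  if (length(unique(firsts)) == 1L) {
    anchor <- firsts[1L]
    ref2 <- substring(ref, 2L)
    alts2 <- substring(alts, 2L)
    alts2[alts2 == ""] <- "-"
    if (ref2 == "") ref2 <- "-"
    start <- pos + 1L
    end <- if (ref2 == "-") pos else pos + nchar(ref2)
    return(list(start = start, end = end, ref = ref2, alts = alts2, anchor = anchor))
  }
  list(start = pos, end = pos + nchar(ref) - 1L, ref = ref, alts = alts,
       anchor = NA_character_)
}

## Restore VCF representation. Returns list(pos, ref, alts).
internal_to_vcf <- function(v, i, genome = NULL) {
  ref <- v$ref_allele[i]; alts <- v$alt_alleles[[i]]
  if (ref != "-" && all(alts != "-") &&
      nchar(ref) == 1L && all(nchar(alts) == 1L))
    return(list(pos = v$start[i], ref = ref, alts = alts))
  anchor <- v$anchor[i]
  if (is.na(anchor)) {
    if (is.null(genome))
      stop("writing indel at ", v$seq_name[i], ":", v$start[i],
           " requires a genome to restore the VCF anchor base")
    anchor <- ref_seq(genome, v$seq_name[i], v$start[i] - 1L)
  }
  ref2 <- if (ref == "-") anchor else paste0(anchor, ref)
  alts2 <- ifelse(alts == "-", anchor, paste0(anchor, alts))
  list(pos = v$start[i] - 1L, ref = ref2, alts = alts2)
}

parse_info_field <- function(info, key) {
  m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
  if (length(m) == 0L) return(NA_character_)
  sub(paste0(".*", key, "="), "", m)
}

#' Read variants from a VCF file
#'
#' One record per VCF row; multi-allelic rows stay one record. Genotype
#' columns, when present, are attached as attribute \code{"gt"} (a matrix of
#' GT strings, variants x samples) for the population-genetics module.
#'
#' @param path VCF v4.x file, plain text or gzip.
#' @param genome optional \code{reference_genome}; when supplied, REF alleles
#'   are validated against it and a mismatch is an error.
#' @return a \code{variant_records} data.frame.
#' @export
read_vcf <- function(path, genome = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  n_header <- length(vcf@meta) + 1L  # meta lines plus #CHROM line
  if (nrow(fix) == 0L)
    return(variant_records(character(0), integer(0), integer(0),
                           character(0), list()))
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  for (i in seq_len(nrow(fix))) {
    line_no <- n_header + i
    if (is.na(pos[i]) || is.na(fix[i, "REF"]) || is.na(fix[i, "ALT"]) ||
        grepl("[^ACGTN]", fix[i, "REF"]))
      stop("malformed VCF row at line ", line_no, " of ", path)
  }
  info <- if ("INFO" %in% colnames(fix)) fix[, "INFO"] else rep(NA_character_, nrow(fix))
  recs <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    vcf_to_internal(pos[i], fix[i, "REF"], alts)
  })
  syn <- lapply(info, function(x) {
    s <- parse_info_field(x %||% "", "SYN")
    if (is.na(s)) character(0) else strsplit(s, ",", fixed = TRUE)[[1]]
  })
  src <- vapply(info, function(x) parse_info_field(x %||% "", "SOURCE"), "")
  strand <- vapply(info, function(x) {
    s <- parse_info_field(x %||% "", "STRAND")
    if (is.na(s)) 1L else as.integer(s)
  }, 1L)
  v <- variant_records(
    seq_name = fix[, "CHROM"],
    start = vapply(recs, `[[`, 1L, "start"),
    end = vapply(recs, `[[`, 1L, "end"),
    ref_allele = vapply(recs, `[[`, "", "ref"),
    alt_alleles = lapply(recs, `[[`, "alts"),
    id = ifelse(fix[, "ID"] == "." | is.na(fix[, "ID"]), NA_character_, fix[, "ID"]),
    synonyms = syn, source = unname(src), strand = strand,
    anchor = vapply(recs, `[[`, "", "anchor"))
  if (!is.null(genome)) {
    for (i in seq_len(nrow(v))) {
      if (v$ref_allele[i] == "-") next
      obs <- ref_seq(genome, v$seq_name[i], v$start[i], v$end[i])
      if (obs != v$ref_allele[i])
        stop("REF allele '", v$ref_allele[i], "' disagrees with reference '",
             obs, "' at ", v$seq_name[i], ":", v$start[i],
             " (VCF line ", n_header + i, ")")
    }
  }
  if (nrow(vcf@gt %||% matrix(nrow = 0, ncol = 0)) > 0L) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    attr(v, "gt") <- gt
  }
  v
}

#' Write variants to a VCF file
#'
#' @param v a \code{variant_records} data.frame. An optional character
#'   column \code{info} supplies per-record INFO content.
#' @param path output file.
#' @param genome optional genome, needed to re-anchor indels read from
#'   non-VCF sources.
#' @param gt optional genotype matrix (variants x samples) of GT strings.
#' @export
write_vcf <- function(v, path, genome = NULL, gt = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=SYN,Number=.,Type=String,Description=\"Synonym identifiers\">",
               "##INFO=<ID=SOURCE,Number=1,Type=String,Description=\"Data source\">",
               "##INFO=<ID=STRAND,Number=1,Type=Integer,Description=\"Strand of report\">"),
             con)
  if (!is.null(gt))
    writeLines("##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">", con)
  hdr <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (!is.null(gt)) hdr <- c(hdr, "FORMAT", colnames(gt))
  writeLines(paste(hdr, collapse = "\t"), con)
  if (nrow(v) > 0L) {
    ord <- order(v$seq_name, v$start)
    for (i in ord) {
      rep_ <- internal_to_vcf(v, i, genome)
      info <- character(0)
      if (length(v$synonyms[[i]]) > 0L)
        info <- c(info, paste0("SYN=", paste(v$synonyms[[i]], collapse = ",")))
      if (!is.na(v$source[i])) info <- c(info, paste0("SOURCE=", v$source[i]))
      if (v$strand[i] != 1L) info <- c(info, paste0("STRAND=", v$strand[i]))
      if (!is.null(v$info) && !is.na(v$info[i]) && nzchar(v$info[i]))
        info <- c(info, v$info[i])
      row <- c(v$seq_name[i], rep_$pos,
               ifelse(is.na(v$id[i]), ".", v$id[i]),
               rep_$ref, paste(rep_$alts, collapse = ","), ".", ".",
               if (length(info)) paste(info, collapse = ";") else ".")
      if (!is.null(gt)) row <- c(row, "GT", gt[i, ])
      writeLines(paste(row, collapse = "\t"), con)
    }
  }
  invisible(path)
}
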