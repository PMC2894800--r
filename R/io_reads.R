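## Aligned reads with per-base PHRED qualities: the unit of evidence for the
## NQS caller. A read-only SAM subset (CIGAR ops M/=/X/I/D/S) and an
## equivalent plain-text table format are supported.

#' Construct a table of aligned reads
#'
#' @param read_id read names.
#' @param seq_name reference sequence per read.
#' @param start genomic position of the leftmost aligned base.
#' @param cigar CIGAR string (ops M, =, X, I, D, S).
#' @param read_seq read sequence.
#' @param quals per-base qualities as PHRED+33 strings (same length as
#'   \code{read_seq}).
#' @param mate_status one of "properly_paired", "improperly_paired",
#'   "unpaired".
#' @param individual sample/strain identifier.
#' @return data.frame of class \code{aligned_reads}.
#' @export
aligned_reads <- function(read_id, seq_name, start, cigar, read_seq, quals,
                          mate_status = "unpaired", individual = "sample") {
  df <- data.frame(read_id = read_id, seq_name = seq_name,
                   start = as.integer(start), cigar = cigar,
                   read_seq = toupper(read_seq), quals = quals,
                   mate_status = rep_len(mate_status, length(read_id)),
                   individual = rep_len(individual, length(read_id)),
                   stringsAsFactors = FALSE)
  bad <- nchar(df$quals) != nchar(df$read_seq)
  if (any(bad))
    stop("quality string length differs from read length: ",
         paste(df$read_id[bad], collapse = ", "))
  ok <- df$mate_status %in% c("properly_paired", "improperly_paired", "unpaired")
  if (!all(ok)) stop("invalid mate_status value(s)")
  for (i in seq_len(nrow(df))) {
    ct <- parse_cigar(df$cigar[i])
    rl <- sum(ct$len[ct$op %in% c("M", "=", "X", "I", "S")])
    if (rl != nchar(df$read_seq[i]))
      stop("CIGAR read-axis length ", rl, " != read length ",
           nchar(df$read_seq[i]), " for ", df$read_id[i])
  }
  class(df) <- c("aligned_reads", "data.frame")
  df
}

parse_cigar <- function(cigar) {
  m <- gregexpr("[0-9]+[MIDSX=]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDSX=]", cigar))[[1]]
  if (length(toks) == 0L || sum(nchar(toks)) != nchar(cigar))
    stop("unsupported or malformed CIGAR: ", cigar)
  list(op = substr(toks, nchar(toks), nchar(toks)),
       len = as.integer(substr(toks, 1L, nchar(toks) - 1L)))
}

#' Expand a read alignment to per-base columns
#'
#' @param read one row of an \code{aligned_reads} table (data.frame row).
#' @param genome a \code{reference_genome}.
#' @return data.frame with one row per aligned read base (CIGAR M/=/X):
#'   \code{read_pos} (1-based on the read), \code{ref_pos},
#'   \code{read_base}, \code{ref_base}, \code{qual} (integer PHRED),
#'   \code{mismatch}.
#' @export
alignment_columns <- function(read, genome) {
  ct <- parse_cigar(read$cigar)
  rp <- 0L; gp <- read$start
  read_pos <- integer(0); ref_pos <- integer(0)
  for (k in seq_along(ct$op)) {
    op <- ct$op[k]; len <- ct$len[k]
    if (op %in% c("M", "=", "X")) {
      read_pos <- c(read_pos, rp + seq_len(len))
      ref_pos <- c(ref_pos, gp + seq_len(len) - 1L)
      rp <- rp + len; gp <- gp + len
    } else if (op %in% c("I", "S")) {
      rp <- rp + len
    } else if (op == "D") {
      gp <- gp + len
    }
  }
  rb <- substring(read$read_seq, read_pos, read_pos)
  fb <- substring(genome$sequences[[read$seq_name]], ref_pos, ref_pos)
  if (!read$seq_name %in% names(genome$sequences))
    stop_coord("read ", read$read_id, " references unknown sequence '",
               read$seq_name, "'")
  q <- phred_to_int(read$quals)[read_pos]
  data.frame(read_pos = read_pos, ref_pos = ref_pos, read_base = rb,
             ref_base = fb, qual = q, mismatch = rb != fb,
             stringsAsFactors = FALSE)
}

## Reference span of each read (leftmost/rightmost aligned reference base).
read_ref_span <- function(reads) {
  ends <- vapply(seq_len(nrow(reads)), function(i) {
    ct <- parse_cigar(reads$cigar[i])
    reads$start[i] + sum(ct$len[ct$op %in% c("M", "=", "X", "D")]) - 1L
  }, 1L)
  data.frame(start = reads$start, end = ends)
}

#' Read a SAM-subset file
#'
#' Plain-text SAM with CIGAR ops M/=/X/I/D/S. Unmapped reads are skipped.
#' Mate status is derived from FLAG bits: paired+proper = properly_paired,
#' paired without proper bit = improperly_paired, else unpaired. The
#' individual is taken from the RG tag (mapped through @RG SM when a header
#' is present), defaulting to "sample".
#'
#' @param path SAM file.
#' @return an \code{aligned_reads} table.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  rg_sm <- character(0)
  for (h in hdr[startsWith(hdr, "@RG")]) {
    f <- strsplit(h, "\t", fixed = TRUE)[[1]]
    id <- sub("^ID:", "", grep("^ID:", f, value = TRUE)[1] %||% NA)
    sm <- sub("^SM:", "", grep("^SM:", f, value = TRUE)[1] %||% NA)
    if (!is.na(id) && !is.na(sm)) rg_sm[id] <- sm
  }
  rows <- lapply(body, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L) stop("malformed SAM line: ", substr(ln, 1, 60))
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) != 0L) return(NULL)  # unmapped
    mate <- if (bitwAnd(flag, 1L) == 0L) "unpaired"
            else if (bitwAnd(flag, 2L) != 0L) "properly_paired"
            else "improperly_paired"
    rg <- sub("^RG:Z:", "", grep("^RG:Z:", f[-(1:11)], value = TRUE)[1] %||% NA)
    ind <- if (!is.na(rg)) unname(rg_sm[rg] %||% rg) else "sample"
    list(read_id = f[1], seq_name = f[3], start = as.integer(f[4]),
         cigar = f[6], read_seq = f[10], quals = f[11],
         mate_status = mate, individual = ind)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L)
    return(aligned_reads(character(0), character(0), integer(0),
                         character(0), character(0), character(0)))
  aligned_reads(
    read_id = vapply(rows, `[[`, "", "read_id"),
    seq_name = vapply(rows, `[[`, "", "seq_name"),
    start = vapply(rows, `[[`, 1L, "start"),
    cigar = vapply(rows, `[[`, "", "cigar"),
    read_seq = vapply(rows, `[[`, "", "read_seq"),
    quals = vapply(rows, `[[`, "", "quals"),
    mate_status = vapply(rows, `[[`, "", "mate_status"),
    individual = vapply(rows, `[[`, "", "individual"))
}

#' Write aligned reads as SAM
#'
#' @param reads an \code{aligned_reads} table.
#' @param path output file.
#' @param genome optional genome for @SQ header lines.
#' @export
write_sam <- function(reads, path, genome = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  if (!is.null(genome))
    for (nm in names(genome$sequences))
      writeLines(paste0("@SQ\tSN:", nm, "\tLN:", genome$lengths[[nm]]), con)
  for (ind in unique(reads$individual))
    writeLines(paste0("@RG\tID:", ind, "\tSM:", ind), con)
  for (i in seq_len(nrow(reads))) {
    flag <- switch(reads$mate_status[i],
                   properly_paired = 3L, improperly_paired = 1L, 0L)
    writeLines(paste(reads$read_id[i], flag, reads$seq_name[i],
                     reads$start[i], 60L, reads$cigar[i], "*", 0L, 0L,
                     reads$read_seq[i], reads$quals[i],
                     paste0("RG:Z:", reads$individual[i]), sep = "\t"), con)
  }
  invisible(path)
}

#' Read aligned reads from a plain-text table
#'
#' Tab-separated with header; columns \code{read_id, seq_name, start, cigar,
#' read_seq, quals, mate_status, individual} (qualities PHRED+33).
#' Equivalent in content to the SAM-subset reader.
#'
#' @param path TSV file.
#' @return an \code{aligned_reads} table.
#' @export
read_reads_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  aligned_reads(df$read_id, df$seq_name, df$start, df$cigar, df$read_seq,
                df$quals, df$mate_status, df$individual)
}

#' Write aligned reads as the plain-text table format
#'
#' @param reads an \code{aligned_reads} table.
#' @param path output file.
#' @export
write_reads_tsv <- function(reads, path) {
  utils::write.table(as.data.frame(reads), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read-coverage ranges in two depth classes
#'
#' Summarizes where an individual's reads align as maximal intervals of
#' constant depth class: "1" (a single read) or "2+" (at least two reads),
#' the threshold used for display of resequencing coverage.
#'
#' @param reads an \code{aligned_reads} table.
#' @param individual optional sample id to subset on.
#' @return data.frame (seq_name, start, end, depth_class), sorted,
#'   non-overlapping.
#' @export
coverage_ranges <- function(reads, individual = NULL) {
  if (!is.null(individual)) reads <- reads[reads$individual == individual, , drop = FALSE]
  out <- list()
  for (sq in sort(unique(reads$seq_name))) {
    r <- reads[reads$seq_name == sq, , drop = FALSE]
    sp <- read_ref_span(r)
    ev <- rbind(data.frame(pos = sp$start, d = 1L),
                data.frame(pos = sp$end + 1L, d = -1L))
    ev <- stats::aggregate(d ~ pos, ev, sum)
    ev <- ev[order(ev$pos), ]
    depth <- cumsum(ev$d)
    seg_start <- ev$pos[-nrow(ev)]
    seg_end <- ev$pos[-1L] - 1L
    cls <- ifelse(depth[-length(depth)] >= 2L, "2+",
                  ifelse(depth[-length(depth)] == 1L, "1", NA))
    keep <- !is.na(cls) & seg_start <= seg_end
    seg <- data.frame(seq_name = sq, start = seg_start[keep],
                      end = seg_end[keep], depth_class = cls[keep],
                      stringsAsFactors = FALSE)
    ## merge adjacent segments of the same class
    if (nrow(seg) > 1L) {
      merged <- seg[1L, ]
      for (i in 2L:nrow(seg)) {
        last <- nrow(merged)
        if (seg$start[i] == merged$end[last] + 1L &&
            seg$depth_class[i] == merged$depth_class[last]) {
          merged$end[last] <- seg$end[i]
        } else merged <- rbind(merged, seg[i, ])
      }
      seg <- merged
    }
    out[[sq]] <- seg
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(seq_name = character(0), start = integer(0),
               end = integer(0), depth_class = character(0))
  rownames(res) <- NULL
  res
}

#' Write coverage ranges to TSV
#'
#' @param ranges data.frame (seq_name, start, end, depth_class) as produced
#'   by \code{\link{coverage_ranges}}; must be non-overlapping.
#' @param path output file.
#' @export
write_coverage_tsv <- function(ranges, path) {
  ranges <- ranges[order(ranges$seq_name, ranges$start), , drop = FALSE]
  for (sq in unique(ranges$seq_name)) {
    r <- ranges[ranges$seq_name == sq, , drop = FALSE]
    if (nrow(r) > 1L && any(r$start[-1L] <= r$end[-nrow(r)]))
      stop("overlapping coverage ranges on ", sq)
  }
  utils::write.table(ranges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
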