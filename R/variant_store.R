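## Variant merging, strand normalization, synonym tracking, and the
## failed-variant QC classifier. All alleles are reported on the forward
## strand; co-located records collapse into a single record whose primary
## identifier prefers dbSNP rs ids, with the rest kept as synonyms.

#' Normalize variant records to the forward strand
#'
#' Records reported on the reverse strand have all alleles
#' reverse-complemented and the strand set to +1. Idempotent.
#'
#' @param v a \code{variant_records} table.
#' @return the normalized table.
#' @export
normalize_strand <- function(v) {
  flip <- which(v$strand == -1L)
  for (i in flip) {
    if (v$ref_allele[i] != "-") v$ref_allele[i] <- revcomp(v$ref_allele[i])
    v$alt_alleles[[i]] <- ifelse(v$alt_alleles[[i]] == "-", "-",
                                 revcomp(v$alt_alleles[[i]]))
    v$strand[i] <- 1L
    v$anchor[i] <- NA_character_  # anchor base no longer meaningful
  }
  v
}

## Identifier class for primary-id preference: dbSNP rs > ss > anything else.
id_rank <- function(id) {
  ifelse(is.na(id), 3L,
         ifelse(grepl("^rs[0-9]+$", id), 1L,
                ifelse(grepl("^ss[0-9]+$", id), 2L, 3L)))
}

empty_merged <- function() {
  df <- data.frame(primary_id = character(0), whitelist = logical(0),
                   stringsAsFactors = FALSE)
  df$synonyms <- list(); df$alleles <- list(); df$mappings <- list()
  df$failed_types <- list()
  class(df) <- c("merged_variants", "data.frame")
  df
}

#' Merge co-located variant records
#'
#' Records sharing an exact genomic location (seq, start, end) collapse into
#' one merged variant: the primary identifier is chosen by source preference
#' (dbSNP rs, then ss, then other ids, ties by natural order), remaining ids
#' become synonyms, and allele sets are unioned. Records sharing a primary
#' id at several locations contribute multiple mappings to one record.
#' Records without a mapping (missing seq/start) yield a merged variant with
#' an empty mapping list. Input must already be strand-normalized.
#'
#' @param vs a \code{variant_records} table (forward strand).
#' @param whitelist character vector of ids exempt from QC failure.
#' @return data.frame of class \code{merged_variants} with list columns
#'   \code{synonyms}, \code{alleles} (ref first), \code{mappings},
#'   \code{failed_types}.
#' @export
merge_variants <- function(vs, whitelist = character(0)) {
  if (nrow(vs) == 0L) return(empty_merged())
  if (any(vs$strand != 1L))
    stop("merge_variants expects strand-normalized input; call normalize_strand() first")
  mapped <- !is.na(vs$seq_name) & !is.na(vs$start)
  key <- ifelse(mapped, paste(vs$seq_name, vs$start, vs$end, sep = ":"),
                paste0("unmapped:", ifelse(is.na(vs$id), seq_len(nrow(vs)), vs$id)))
  groups <- split(seq_len(nrow(vs)), key)
  loci <- lapply(groups, function(idx) {
    ids <- unique(c(stats::na.omit(vs$id[idx]),
                    unlist(vs$synonyms[idx], use.names = FALSE)))
    ids <- ids[order(id_rank(ids), ids)]
    primary <- if (length(ids)) ids[1L] else NA_character_
    alleles <- unique(c(vs$ref_allele[idx][1L],
                        unlist(vs$alt_alleles[idx], use.names = FALSE)))
    i1 <- idx[1L]
    list(primary = primary, synonyms = setdiff(ids, primary),
         alleles = alleles,
         mapping = if (mapped[i1])
           data.frame(seq_name = vs$seq_name[i1], start = vs$start[i1],
                      end = vs$end[i1], stringsAsFactors = FALSE)
         else data.frame(seq_name = character(0), start = integer(0),
                         end = integer(0)))
  })
  ## second pass: one record per primary id, unioning mappings
  pkey <- vapply(loci, function(l) l$primary %||% NA_character_, "")
  pkey[is.na(pkey)] <- paste0("anon:", which(is.na(pkey)))
  pgroups <- split(seq_along(loci), pkey)
  rows <- lapply(pgroups, function(li) {
    ls <- loci[li]
    maps <- do.call(rbind, lapply(ls, `[[`, "mapping"))
    maps <- unique(maps[order(maps$seq_name, maps$start), , drop = FALSE])
    rownames(maps) <- NULL
    list(primary_id = ls[[1L]]$primary,
         synonyms = unique(unlist(lapply(ls, `[[`, "synonyms"))),
         alleles = unique(unlist(lapply(ls, `[[`, "alleles"))),
         mappings = maps)
  })
  df <- data.frame(
    primary_id = vapply(rows, function(r) r$primary_id %||% NA_character_, ""),
    whitelist = FALSE, stringsAsFactors = FALSE)
  df$synonyms <- lapply(rows, `[[`, "synonyms")
  df$alleles <- lapply(rows, `[[`, "alleles")
  df$mappings <- lapply(rows, `[[`, "mappings")
  df$failed_types <- rep(list(character(0)), nrow(df))
  df$whitelist <- df$primary_id %in% whitelist
  df <- df[order(id_rank(df$primary_id), df$primary_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("merged_variants", "data.frame")
  df
}

#' Failed-variant classification
#'
#' A merged variant is flagged unreliable if it maps more than
#' \code{max_mappings} times (MAPS_GT3), does not map at all (NO_MAPPING),
#' has no observed allele matching the reference allele at any mapping
#' (NO_REF_ALLELE_MATCH), or has more than \code{max_alleles} observed
#' alleles (GT3_ALLELES). Whitelisted variants are never moved to the
#' failed set. An OTHER flag value is reserved for future checks.
#'
#' @param mv one row of a \code{merged_variants} table, or the whole table
#'   (classified row-wise, updating \code{failed_types}).
#' @param genome a \code{reference_genome}.
#' @param max_mappings,max_alleles failure thresholds.
#' @return for a single row, the character set of failure types; for a
#'   table, the table with \code{failed_types} filled in.
#' @export
classify_failed <- function(mv, genome, max_mappings = 3L, max_alleles = 3L) {
  classify_one <- function(row) {
    if (row$whitelist) return(character(0))
    flags <- character(0)
    maps <- row$mappings[[1L]]
    if (nrow(maps) > max_mappings) flags <- c(flags, "MAPS_GT3")
    if (nrow(maps) == 0L) flags <- c(flags, "NO_MAPPING")
    if (nrow(maps) > 0L) {
      match_any <- FALSE
      for (m in seq_len(nrow(maps))) {
        refb <- if (maps$start[m] == maps$end[m] + 1L) "-" else
          ref_seq(genome, maps$seq_name[m], maps$start[m], maps$end[m])
        if (refb %in% row$alleles[[1L]]) { match_any <- TRUE; break }
      }
      if (!match_any) flags <- c(flags, "NO_REF_ALLELE_MATCH")
    }
    if (length(row$alleles[[1L]]) > max_alleles) flags <- c(flags, "GT3_ALLELES")
    flags
  }
  if (nrow(mv) == 1L) return(classify_one(mv))
  mv$failed_types <- lapply(seq_len(nrow(mv)), function(i)
    classify_one(mv[i, , drop = FALSE]))
  mv
}

#' Variants passing QC
#'
#' Failed variants stay in the store but carry no displayed mapping; this
#' helper returns the reliable subset (empty failure set, or whitelisted)
#' for downstream consequence annotation and LD.
#'
#' @param mv a classified \code{merged_variants} table.
#' @return the passing subset.
#' @export
passing_variants <- function(mv) {
  keep <- vapply(seq_len(nrow(mv)), function(i)
    mv$whitelist[i] || length(mv$failed_types[[i]]) == 0L, TRUE)
  out <- mv[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merged variants as single-mapping variant records
#'
#' Expands passing merged variants (one row per mapping) back into a
#' \code{variant_records} table for annotation and VCF output. Alleles
#' beyond the reference become the alt set.
#'
#' @param mv a \code{merged_variants} table.
#' @param genome a \code{reference_genome} used to identify which allele is
#'   the reference at each mapping.
#' @return a \code{variant_records} table.
#' @export
merged_to_records <- function(mv, genome) {
  rows <- list()
  for (i in seq_len(nrow(mv))) {
    maps <- mv$mappings[[i]]
    for (m in seq_len(nrow(maps))) {
      refb <- if (maps$start[m] == maps$end[m] + 1L) "-" else
        ref_seq(genome, maps$seq_name[m], maps$start[m], maps$end[m])
      alts <- setdiff(mv$alleles[[i]], refb)
      if (length(alts) == 0L) next
      rows[[length(rows) + 1L]] <- variant_records(
        maps$seq_name[m], maps$start[m], maps$end[m], refb, list(alts),
        id = mv$primary_id[i], synonyms = list(mv$synonyms[[i]]))
    }
  }
  if (length(rows) == 0L)
    return(variant_records(character(0), integer(0), integer(0),
                           character(0), list()))
  out <- do.call(rbind, rows)
  class(out) <- c("variant_records", "data.frame")
  out
}
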