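## Population-genetic post-processing: minor allele frequencies, two-locus
## EM haplotype-frequency estimation (r2, D'), windowed pairwise LD, and
## greedy MAF-ordered tag-SNP selection.

#' Construct a genotype matrix
#'
#' Unphased diploid genotypes for one population at biallelic variants.
#' Genotypes are coded as the count of the second allele (0, 1, 2) with NA
#' for missing.
#'
#' @param population_id population label.
#' @param samples character vector of sample ids.
#' @param variants data.frame with columns \code{variant_id, seq_name, pos,
#'   allele_1, allele_2}.
#' @param geno integer matrix, variants x samples, values 0/1/2/NA.
#' @return object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(population_id, samples, variants, geno) {
  geno <- as.matrix(geno)
  if (nrow(geno) != nrow(variants) || ncol(geno) != length(samples))
    stop("genotype table dimensions must match variants x samples")
  if (!all(geno %in% c(0L, 1L, 2L, NA)))
    stop("genotypes must be 0, 1, 2 or NA")
  rownames(geno) <- variants$variant_id
  colnames(geno) <- samples
  structure(list(population_id = population_id, samples = samples,
                 variants = variants, geno = geno),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix '", x$population_id, "': ", length(x$samples),
      " samples x ", nrow(x$variants), " variants\n", sep = "")
  invisible(x)
}

#' Build a genotype matrix from VCF genotype columns
#'
#' Keeps biallelic variants only (multi-allelic rows are dropped with a
#' warning). GT fields may be phased or unphased; anything non-numeric is
#' treated as missing.
#'
#' @param v a \code{variant_records} table carrying a \code{"gt"} attribute
#'   (as returned by \code{\link{read_vcf}} on a VCF with samples).
#' @param population_id population label.
#' @param samples optional subset of sample ids.
#' @return a \code{genotype_matrix}.
#' @export
vcf_genotype_matrix <- function(v, population_id = "population",
                                samples = NULL) {
  gt <- attr(v, "gt")
  if (is.null(gt)) stop("variant table carries no genotype columns")
  if (is.null(samples)) samples <- colnames(gt)
  gt <- gt[, samples, drop = FALSE]
  biallelic <- vapply(v$alt_alleles, length, 1L) == 1L
  if (any(!biallelic))
    warning(sum(!biallelic), " multi-allelic variant(s) dropped from genotype matrix")
  idx <- which(biallelic)
  code <- function(s) {
    a <- strsplit(gsub("\\|", "/", s), "/", fixed = TRUE)
    vapply(a, function(x) {
      x <- suppressWarnings(as.integer(x))
      if (length(x) != 2L || anyNA(x)) NA_integer_ else sum(x)
    }, 1L)
  }
  geno <- t(vapply(idx, function(i) code(gt[i, ]), integer(length(samples))))
  if (length(samples) == 1L) geno <- matrix(geno, ncol = 1L)
  ids <- ifelse(is.na(v$id[idx]), paste0(v$seq_name[idx], ":", v$start[idx]),
                v$id[idx])
  vars <- data.frame(variant_id = ids, seq_name = v$seq_name[idx],
                     pos = v$start[idx],
                     allele_1 = v$ref_allele[idx],
                     allele_2 = vapply(v$alt_alleles[idx], `[`, "", 1L),
                     stringsAsFactors = FALSE)
  genotype_matrix(population_id, samples, vars, geno)
}

variant_index <- function(g, variant) {
  if (is.numeric(variant)) return(as.integer(variant))
  i <- match(variant, g$variants$variant_id)
  if (is.na(i)) stop("unknown variant '", variant, "'")
  i
}

#' Minor allele frequency
#'
#' Minor-allele count over twice the number of non-missing samples.
#'
#' @param g a \code{genotype_matrix}.
#' @param variant variant id or index.
#' @return frequency in [0, 0.5].
#' @export
maf <- function(g, variant) {
  x <- g$geno[variant_index(g, variant), ]
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("MAF undefined: all genotypes missing")
  f <- sum(x) / (2 * length(x))
  min(f, 1 - f)
}

## 3x3 genotype-class counts over pairwise-complete samples.
pair_counts <- function(g, v1, v2) {
  x <- g$geno[variant_index(g, v1), ]
  y <- g$geno[variant_index(g, v2), ]
  ok <- !is.na(x) & !is.na(y)
  n <- matrix(0L, 3L, 3L)
  for (k in which(ok)) n[x[k] + 1L, y[k] + 1L] <- n[x[k] + 1L, y[k] + 1L] + 1L
  n
}

## Multinomial log-likelihood of 3x3 genotype counts given haplotype
## frequencies p = (AB, Ab, aB, ab), where A/B are the allele-1 labels.
two_locus_loglik <- function(p, n) {
  P <- matrix(c(p[1]^2,        2 * p[1] * p[2],             p[2]^2,
                2 * p[1] * p[3], 2 * (p[1] * p[4] + p[2] * p[3]), 2 * p[2] * p[4],
                p[3]^2,        2 * p[3] * p[4],             p[4]^2),
              3L, 3L, byrow = TRUE)
  use <- n > 0L
  sum(n[use] * log(pmax(P[use], 1e-300)))
}

ld_stats <- function(p) {
  pA <- p[1] + p[2]; pB <- p[1] + p[3]
  pa <- 1 - pA; pb <- 1 - pB
  D <- p[1] - pA * pB
  d_max <- if (D > 0) min(pA * pb, pa * pB) else min(pA * pB, pa * pb)
  d_prime <- if (D == 0 || d_max == 0) 0 else D / d_max
  r2 <- if (pA * pa * pB * pb == 0) NA_real_ else D^2 / (pA * pa * pB * pb)
  list(D = D, d_prime = d_prime, r2 = r2, pA = pA, pB = pB)
}

#' Two-locus haplotype frequencies by EM
#'
#' Estimates the four haplotype frequencies from unphased diploid genotypes.
#' Only double heterozygotes are phase-ambiguous: the E-step splits them
#' between the coupling (AB/ab) and repulsion (Ab/aB) configurations in
#' ratio p_AB p_ab : p_Ab p_aB; the M-step re-estimates frequencies from
#' expected haplotype counts. Initialization is at linkage equilibrium
#' (products of allele frequencies). From the converged frequencies:
#' D = p_AB - p_A p_B; D' = D / D_max with D_max = min(p_A p_b, p_a p_B) for
#' D > 0 and min(p_A p_B, p_a p_b) for D < 0 (0 at D = 0);
#' r2 = D^2 / (p_A p_a p_B p_b).
#'
#' @param g a \code{genotype_matrix}.
#' @param v1,v2 variant ids or indices.
#' @param tol convergence tolerance on the maximum frequency change.
#' @param max_iter iteration cap.
#' @return list of class \code{ld_result}: haplotype frequencies \code{p}
#'   (AB, Ab, aB, ab), \code{D}, \code{d_prime} (absolute),
#'   \code{d_prime_signed}, \code{r2}, \code{n_informative}, the
#'   \code{loglik} trace, and the variant pair. NULL (with attribute
#'   \code{"excluded"}) when either locus is monomorphic among the
#'   pairwise-complete samples.
#' @export
em_haplotypes <- function(g, v1, v2, tol = 1e-9, max_iter = 1000L) {
  n <- pair_counts(g, v1, v2)
  n_inf <- sum(n)
  if (n_inf == 0L) return(structure(list(), excluded = "no informative samples"))
  ## marginal allele frequencies are fixed by the genotype counts
  pA <- sum(n * (2 - (row(n) - 1))) / (2 * n_inf)
  pB <- sum(n * (2 - (col(n) - 1))) / (2 * n_inf)
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    return(structure(list(), excluded = "monomorphic locus"))
  p <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  loglik <- two_locus_loglik(p, n)
  n_dh <- n[2L, 2L]
  for (it in seq_len(max_iter)) {
    denom <- p[1] * p[4] + p[2] * p[3]
    w <- if (denom == 0) 0.5 else p[1] * p[4] / denom
    cAB <- 2 * n[1, 1] + n[1, 2] + n[2, 1] + w * n_dh
    cAb <- 2 * n[1, 3] + n[1, 2] + n[2, 3] + (1 - w) * n_dh
    caB <- 2 * n[3, 1] + n[2, 1] + n[3, 2] + (1 - w) * n_dh
    cab <- 2 * n[3, 3] + n[3, 2] + n[2, 3] + w * n_dh
    p_new <- c(cAB, cAb, caB, cab) / (2 * n_inf)
    delta <- max(abs(p_new - p))
    p <- p_new
    loglik <- c(loglik, two_locus_loglik(p, n))
    if (delta < tol) break
  }
  s <- ld_stats(p)
  ids <- g$variants$variant_id[c(variant_index(g, v1), variant_index(g, v2))]
  structure(list(variant_pair = ids,
                 p = stats::setNames(p, c("AB", "Ab", "aB", "ab")),
                 D = s$D, d_prime = abs(s$d_prime), d_prime_signed = s$d_prime,
                 r2 = s$r2, n_informative = n_inf, loglik = loglik),
            class = "ld_result")
}

#' Pairwise LD within a genomic window
#'
#' Computes \code{\link{em_haplotypes}} for every same-sequence variant pair
#' at most \code{window} bp apart. Pairs with r2 below \code{min_r2_store}
#' are discarded (the stored table feeds tag-SNP selection only). Returns an
#' empty table with a warning when the population has fewer than
#' \code{min_samples} samples.
#'
#' @param g a \code{genotype_matrix}.
#' @param window window size in bp.
#' @param min_r2_store storage threshold on r2.
#' @param min_samples minimum population sample size.
#' @return data.frame: id1, id2, seq_name, pos1, pos2, distance, D, d_prime,
#'   r2, n_informative.
#' @export
windowed_ld <- function(g, window = 100000L, min_r2_store = 0.05,
                        min_samples = 40L) {
  empty <- data.frame(id1 = character(0), id2 = character(0),
                      seq_name = character(0), pos1 = integer(0),
                      pos2 = integer(0), distance = integer(0),
                      D = numeric(0), d_prime = numeric(0), r2 = numeric(0),
                      n_informative = integer(0), stringsAsFactors = FALSE)
  if (length(g$samples) < min_samples) {
    warning("population '", g$population_id, "' has ", length(g$samples),
            " samples (< ", min_samples, "); no LD computed")
    return(empty)
  }
  ord <- order(g$variants$seq_name, g$variants$pos)
  rows <- list()
  for (a in seq_along(ord)) {
    for (b in seq_len(a - 1L)) {
      i <- ord[b]; j <- ord[a]
      if (g$variants$seq_name[i] != g$variants$seq_name[j]) next
      dist <- abs(g$variants$pos[j] - g$variants$pos[i])
      if (dist > window) next
      res <- em_haplotypes(g, i, j)
      if (!inherits(res, "ld_result") || is.na(res$r2)) next
      if (res$r2 < min_r2_store) next
      rows[[length(rows) + 1L]] <- data.frame(
        id1 = g$variants$variant_id[i], id2 = g$variants$variant_id[j],
        seq_name = g$variants$seq_name[i], pos1 = g$variants$pos[i],
        pos2 = g$variants$pos[j], distance = dist, D = res$D,
        d_prime = res$d_prime, r2 = res$r2,
        n_informative = res$n_informative, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$seq_name, out$pos1, out$pos2), , drop = FALSE]
}

#' Greedy tag-SNP selection
#'
#' Variants with genotypes are ranked by MAF (highest first, ties by
#' ascending position). Walking down that ranking, each still-retained
#' variant removes every other retained variant within \code{window} bp
#' whose pairwise r2 with it exceeds \code{r2_cut} (those variants have
#' lower MAF, or equal MAF and a later ranking). Survivors are the tag
#' SNPs.
#'
#' @param g a \code{genotype_matrix}.
#' @param ld LD table from \code{\link{windowed_ld}} on the same matrix.
#' @param r2_cut r2 above which a pair is "high LD".
#' @param window window size in bp.
#' @return character vector of tag-SNP variant ids in position order.
#' @export
select_tag_snps <- function(g, ld, r2_cut = 0.99, window = 100000L) {
  v <- g$variants
  mafs <- vapply(seq_len(nrow(v)), function(i) {
    x <- g$geno[i, ]
    if (all(is.na(x))) NA_real_ else maf(g, i)
  }, 1)
  has_geno <- !is.na(mafs)
  ord <- order(-mafs[has_geno], v$pos[has_geno])
  idx <- which(has_geno)[ord]
  key <- function(a, b) paste(sort(c(a, b)), collapse = "\r")
  r2_of <- stats::setNames(ld$r2, mapply(key, ld$id1, ld$id2))
  retained <- rep(TRUE, nrow(v))
  for (k in seq_along(idx)) {
    i <- idx[k]
    if (!retained[i]) next
    for (m in seq_along(idx)) {
      j <- idx[m]
      if (m == k || !retained[j]) next
      if (v$seq_name[i] != v$seq_name[j]) next
      if (abs(v$pos[i] - v$pos[j]) > window) next
      r2 <- r2_of[key(v$variant_id[i], v$variant_id[j])]
      if (!is.na(r2) && r2 > r2_cut && m > k) retained[j] <- FALSE
    }
  }
  ids <- v$variant_id[retained & has_geno]
  ids[order(v$seq_name[retained & has_geno], v$pos[retained & has_geno])]
}

#' Write an LD table to TSV
#'
#' @param ld LD table from \code{\link{windowed_ld}}.
#' @param path output file.
#' @export
write_ld_tsv <- function(ld, path) {
  utils::write.table(ld, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export pairwise LD in a Haploview-compatible layout
#'
#' Columns L1, L2, D', LOD, r^2, CIlo, CIhi, Dist, T-int; LOD and the D'
#' confidence interval are not computed and are written as 0.
#'
#' @param ld LD table from \code{\link{windowed_ld}}.
#' @param path output file.
#' @export
write_haploview_ld <- function(ld, path) {
  df <- data.frame(L1 = ld$id1, L2 = ld$id2, "D'" = round(ld$d_prime, 3),
                   LOD = 0, "r^2" = round(ld$r2, 3), CIlo = 0, CIhi = 0,
                   Dist = ld$distance, "T-int" = 0, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
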