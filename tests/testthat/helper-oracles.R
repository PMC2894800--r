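## Independent brute-force oracles, written against the rule text rather
## than the package's internals, plus small fixture builders.

## ---- small handmade fixtures ------------------------------------------

## A deterministic 400 bp genome and a family of transcripts used across
## module tests.
tiny_genome <- function(seed = 42L, len = 400L, name = "chrT") {
  set.seed(seed)
  reference_genome(stats::setNames(
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    name))
}

## plus-strand coding transcript: exons 41-100, 121-200, 241-300; CDS 61-280
tiny_tx_plus <- function() transcript_model(
  "TP", "GP", "chrT", 1L,
  rbind(c(41L, 100L), c(121L, 200L), c(241L, 300L)),
  cds_start = 61L, cds_end = 280L)

tiny_tx_minus <- function() transcript_model(
  "TM", "GM", "chrT", -1L,
  rbind(c(41L, 100L), c(121L, 200L), c(241L, 300L)),
  cds_start = 61L, cds_end = 280L)

## build a genotype_matrix from genotype-count vectors (one per variant)
make_gm <- function(..., pos = NULL, seq_name = "chr1", pop = "TESTPOP") {
  gl <- list(...)
  n <- length(gl[[1L]])
  if (is.null(pos)) pos <- 100L * seq_along(gl)
  vars <- data.frame(variant_id = paste0("v", seq_along(gl)),
                     seq_name = seq_name, pos = as.integer(pos),
                     allele_1 = "A", allele_2 = "G", stringsAsFactors = FALSE)
  genotype_matrix(pop, paste0("s", seq_len(n)), vars,
                  do.call(rbind, gl))
}

## ---- consequence oracle ------------------------------------------------

## Per-base SNV classifier: explicit scans over exon tables, full-protein
## translation via Biostrings on a mutated genome copy. Returns a single
## consequence label or NULL when the position is out of the 5 kb scope.
oracle_classify_snv <- function(pos, alt, t, genome, flank = 5000L) {
  ex <- t$exons
  n_ex <- nrow(ex)
  span <- c(ex[1L, 1L], ex[n_ex, 2L])
  if (pos < span[1L] || pos > span[2L]) {
    d <- if (pos < span[1L]) span[1L] - pos else pos - span[2L]
    if (d > flank) return(NULL)
    left <- pos < span[1L]
    if (t$strand == 1L) return(if (left) "Upstream" else "Downstream")
    return(if (left) "Downstream" else "Upstream")
  }
  exon_i <- 0L
  for (i in seq_len(n_ex))
    if (pos >= ex[i, 1L] && pos <= ex[i, 2L]) exon_i <- i
  if (exon_i == 0L) {
    ## intronic: distance to the nearest exon edge
    d <- min(abs(c(pos - ex[, 1L], pos - ex[, 2L])))
    if (d <= 2L) return("Essential splice site, intronic")
    if (d <= 8L) return("Splice site, intronic")
    return("Intronic")
  }
  if (is.na(t$cds_start)) {
    if (!is.null(t$mature_mirna) &&
        any(pos >= t$mature_mirna[, 1L] & pos <= t$mature_mirna[, 2L]))
      return("Within mature miRNA")
    return("Within non-coding gene")
  }
  ## splice modifier: 1-3 bp from an intron-adjacent exon edge
  dd <- integer(0)
  if (exon_i > 1L) dd <- c(dd, pos - ex[exon_i, 1L] + 1L)
  if (exon_i < n_ex) dd <- c(dd, ex[exon_i, 2L] - pos + 1L)
  splice <- length(dd) > 0L && min(dd) <= 3L
  ## spliced positions in transcript orientation, built independently
  gp <- integer(0)
  for (i in seq_len(n_ex)) gp <- c(gp, ex[i, 1L]:ex[i, 2L])
  if (t$strand < 0L) gp <- rev(gp)
  in_cds <- gp >= t$cds_start & gp <= t$cds_end
  if (!(pos >= t$cds_start && pos <= t$cds_end)) {
    before_cds <- which(gp == pos) < min(which(in_cds))
    base <- if (before_cds) "5' UTR" else "3' UTR"
    return(if (splice) paste0("Splice site, ", base) else base)
  }
  ## CDS SNV: mutate a genome copy, translate both CDS sequences fully
  extract_cds <- function(seqstr) {
    parts <- character(0)
    for (i in seq_len(n_ex)) {
      s <- max(ex[i, 1L], t$cds_start); e <- min(ex[i, 2L], t$cds_end)
      if (s <= e) parts <- c(parts, substr(seqstr, s, e))
    }
    s <- paste(parts, collapse = "")
    if (t$strand < 0L)
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }
  refstr <- genome$sequences[[t$seq_name]]
  altstr <- refstr
  substr(altstr, pos, pos) <- alt
  tr <- function(s) {
    n3 <- (nchar(s) %/% 3L) * 3L
    as.character(suppressWarnings(
      Biostrings::translate(Biostrings::DNAString(substr(s, 1L, n3)))))
  }
  ref_p <- tr(extract_cds(refstr))
  alt_p <- tr(extract_cds(altstr))
  cds_positions <- gp[in_cds]
  cds_pos <- which(cds_positions == pos)
  ci <- (cds_pos - 1L) %/% 3L + 1L
  base <- if (ci > nchar(ref_p)) "Synonymous coding"   # incomplete last codon
    else {
      ra <- substr(ref_p, ci, ci); aa <- substr(alt_p, ci, ci)
      if (aa == "*" && ra != "*") "Stop gained"
      else if (ra == "*" && aa != "*") "Stop lost"
      else if (ra == aa) "Synonymous coding"
      else "Non-synonymous coding"
    }
  if (!splice) return(base)
  switch(base,
         "Stop gained" = "Stop gained, splice site",
         "Stop lost" = "Stop lost, splice site",
         "Synonymous coding" = "Splice site, synonymous coding",
         "Non-synonymous coding" = "Non-synonymous coding, splice site")
}

## ---- caller oracle -----------------------------------------------------

## Literal restatement of the calling rules, with its own CIGAR expansion.
## Returns a data.frame (seq_name, pos, individual, alleles, counts-string).
oracle_expand_read <- function(read, genome) {
  toks <- regmatches(read$cigar, gregexpr("[0-9]+[MIDSX=]", read$cigar))[[1]]
  ops <- substr(toks, nchar(toks), nchar(toks))
  lens <- as.integer(sub(".$", "", toks))
  q <- as.integer(charToRaw(read$quals)) - 33L
  rpos <- 0L; gpos <- read$start
  res <- NULL
  for (k in seq_along(ops)) {
    if (ops[k] %in% c("M", "=", "X")) {
      for (u in seq_len(lens[k])) {
        res <- rbind(res, data.frame(
          rp = rpos + u, gp = gpos + u - 1L,
          base = substr(read$read_seq, rpos + u, rpos + u),
          qual = q[rpos + u], stringsAsFactors = FALSE))
      }
      rpos <- rpos + lens[k]; gpos <- gpos + lens[k]
    } else if (ops[k] %in% c("I", "S")) rpos <- rpos + lens[k]
    else if (ops[k] == "D") gpos <- gpos + lens[k]
  }
  res$refb <- vapply(res$gp, function(p)
    substr(genome$sequences[[read$seq_name]], p, p), "")
  res
}

oracle_nqs <- function(tab, rp, cfg) {
  i <- which(tab$rp == rp)
  if (length(i) == 0L) return(FALSE)
  if (tab$qual[i] < cfg$min_variant_phred) return(FALSE)
  for (k in 1:cfg$exact_flank_bp) for (s in c(-1L, 1L)) {
    j <- which(tab$rp == rp + s * k)
    if (length(j) == 0L) return(FALSE)
    if (tab$gp[j] != tab$gp[i] + s * k) return(FALSE)
    if (tab$base[j] != tab$refb[j]) return(FALSE)
    if (tab$qual[j] <= cfg$min_flank_phred) return(FALSE)
  }
  w <- tab$rp >= rp - cfg$mismatch_window_bp &
       tab$rp <= rp + cfg$mismatch_window_bp & tab$rp != rp
  sum(tab$base[w] != tab$refb[w]) <= cfg$max_flank_mismatches
}

oracle_call_snps <- function(reads, genome, cfg = caller_config(),
                             coverage = 1) {
  sc <- if (coverage < cfg$low_coverage_threshold) cfg$low_coverage_scale else 1
  max_rm <- floor(cfg$max_read_mismatches * sc)
  max_depth <- floor(cfg$max_site_depth * sc)
  out <- NULL
  for (ind in sort(unique(reads$individual))) {
    rs <- reads[reads$individual == ind &
                reads$mate_status != "improperly_paired", , drop = FALSE]
    if (nrow(rs) == 0L) next
    tabs <- lapply(seq_len(nrow(rs)), function(i)
      oracle_expand_read(rs[i, ], genome))
    keep <- vapply(tabs, function(tb) sum(tb$base != tb$refb) <= max_rm, TRUE)
    rs <- rs[keep, , drop = FALSE]; tabs <- tabs[keep]
    if (nrow(rs) == 0L) next
    all_pos <- sort(unique(unlist(lapply(tabs, function(tb)
      tb$gp[tb$base != tb$refb]))))
    for (p in all_pos) {
      cov <- which(vapply(tabs, function(tb) p %in% tb$gp, TRUE))
      if (length(cov) > max_depth) next
      bases <- character(0)
      for (ri in cov) {
        tb <- tabs[[ri]]
        if (oracle_nqs(tb, tb$rp[tb$gp == p], cfg))
          bases <- c(bases, tb$base[tb$gp == p])
      }
      if (length(bases) == 0L) next
      ref <- substr(genome$sequences[[rs$seq_name[1]]], p, p)
      tab <- table(bases)
      if (length(tab) > cfg$max_alleles_per_individual) next
      if (!any(names(tab) != ref)) next
      if (sum(tab) >= cfg$min_depth_for_minor_rule && length(tab) >= 2L &&
          min(tab) < cfg$min_minor_reads) next
      out <- rbind(out, data.frame(
        seq_name = rs$seq_name[1], pos = p, individual = ind,
        alleles = paste(sort(names(tab)), collapse = "/"),
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) out <- data.frame(seq_name = character(0), pos = integer(0),
                                      individual = character(0),
                                      alleles = character(0))
  out[order(out$seq_name, out$pos, out$individual), , drop = FALSE]
}

## ---- LD grid-search oracle --------------------------------------------

## Maximum of the two-locus multinomial likelihood over p_AB on a fixed
## grid (margins are fixed by the genotype counts). Returns r2 and D'.
oracle_grid_ld <- function(g1, g2, step = 1e-3) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  n <- matrix(0L, 3L, 3L)
  for (k in seq_along(g1)) n[g1[k] + 1L, g2[k] + 1L] <- n[g1[k] + 1L, g2[k] + 1L] + 1L
  N <- sum(n)
  pA <- sum((2 - (row(n) - 1)) * n) / (2 * N)
  pB <- sum((2 - (col(n) - 1)) * n) / (2 * N)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(NULL)
  lo0 <- max(0, pA + pB - 1); hi0 <- min(pA, pB)
  ll_of <- function(pAB) {
    p <- c(pAB, pA - pAB, pB - pAB, 1 - pA - pB + pAB)
    P <- matrix(c(p[1]^2, 2 * p[1] * p[2], p[2]^2,
                  2 * p[1] * p[3], 2 * (p[1] * p[4] + p[2] * p[3]), 2 * p[2] * p[4],
                  p[3]^2, 2 * p[3] * p[4], p[4]^2), 3L, 3L, byrow = TRUE)
    sum(n[n > 0] * log(pmax(P[n > 0], 1e-300)))
  }
  ## dense grid, then refined grids around the maximum (the raw 1e-3 grid
  ## quantizes p_AB by +-step/2, too coarse to compare r2 at 1e-4)
  lo <- lo0; hi <- hi0; st <- step; pAB <- lo0
  for (round in 1:3) {
    grid <- unique(c(seq(lo, hi, by = st), hi))
    pAB <- grid[which.max(vapply(grid, ll_of, 1))]
    lo <- max(lo0, pAB - st); hi <- min(hi0, pAB + st); st <- st / 100
  }
  D <- pAB - pA * pB
  dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB) else min(pA * pB, (1 - pA) * (1 - pB))
  list(p_AB = pAB, D = D,
       d_prime = if (D == 0 || dmax == 0) 0 else abs(D / dmax),
       r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)))
}

## simulate genotypes for one pair from haplotype frequencies
sim_pair_genotypes <- function(freqs, n) {
  hap <- rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
  h1 <- sample.int(4L, n, replace = TRUE, prob = freqs)
  h2 <- sample.int(4L, n, replace = TRUE, prob = freqs)
  list(g1 = hap[h1, 1L] + hap[h2, 1L], g2 = hap[h1, 2L] + hap[h2, 2L])
}

## ---- tag-SNP oracle ----------------------------------------------------

## Literal restatement of the greedy MAF-ordered pruning.
oracle_tags <- function(vars, ld, r2_cut = 0.99, window = 100000L) {
  key <- function(a, b) paste(sort(c(a, b)), collapse = "\r")
  r2_of <- stats::setNames(ld$r2, mapply(key, ld$id1, ld$id2))
  ord <- order(-vars$maf, vars$pos)
  retained <- rep(TRUE, nrow(vars))
  for (k in seq_along(ord)) {
    i <- ord[k]
    if (!retained[i]) next
    for (m in seq_along(ord)) {
      j <- ord[m]
      if (m == k || !retained[j]) next
      if (vars$seq_name[i] != vars$seq_name[j]) next
      if (abs(vars$pos[i] - vars$pos[j]) > window) next
      r2 <- r2_of[key(vars$id[i], vars$id[j])]
      if (!is.na(r2) && r2 > r2_cut && m > k) retained[j] <- FALSE
    }
  }
  vars$id[retained][order(vars$pos[retained])]
}

## ---- sweep fixture -----------------------------------------------------

## A coding transcript engineered so that every SNV-reachable consequence
## class occurs somewhere in a per-base sweep: CDS bases at 1-3 bp from
## splice junctions carry Trp (TGG) and Leu (CTG) codons (stop-gain and
## synonymous changes at the junction), the terminal stop TAA sits 1-3 bp
## from the last junction, UTR bases flank junctions on both sides, and a
## miRNA gene plus a regulatory feature sit downstream.
build_sweep_fixture <- function(seed = 99L) {
  B <- 5100L
  len <- 12000L
  set.seed(seed)
  s <- paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
  exons <- B + rbind(c(101L, 200L), c(221L, 320L), c(341L, 440L),
                     c(461L, 560L))
  cds_start <- B + 226L; cds_end <- B + 440L
  put <- function(pos3, codon) for (k in 1:3)
    substr(s, pos3[k], pos3[k]) <<- substr(codon, k, k)
  put(B + c(283L, 284L, 285L), "TGG")   # codon 20, mid-exon: plain stop gained
  put(B + c(319L, 320L, 341L), "TGG")   # codon 32 spans a junction: stop gained, splice site
  put(B + c(342L, 343L, 344L), "CTG")   # codon 33: splice site, synonymous (CTG->TTG)
  put(B + c(438L, 439L, 440L), "TAA")   # terminal codon at the junction: stop lost, splice site
  genome <- reference_genome(stats::setNames(s, "chrS"))
  txc <- transcript_model("TXC", "GC", "chrS", 1L, exons,
                          cds_start = cds_start, cds_end = cds_end)
  mir <- transcript_model("MIR", "GMIR", "chrS", 1L,
                          rbind(B + c(700L, 800L)), biotype = "miRNA",
                          mature_mirna = rbind(B + c(730L, 750L)))
  regs <- regulatory_features("chrS", B + 150L, B + 170L, "GC")
  list(genome = genome, txc = txc, mir = mir, regs = regs, B = B)
}
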