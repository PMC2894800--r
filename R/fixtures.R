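## Deterministic synthetic-data generator: a random reference with coding,
## minus-strand and miRNA transcripts, quality-scored reads with planted
## heterozygous SNPs, and population genotypes drawn from known two-locus
## haplotype frequencies. Every output is reproducible from the seed; truth
## tables are emitted so downstream modules can be scored.

#' Fixture specification
#'
#' Defaults describe a small but fully featured study: a 20 kb reference,
#' a 3-exon plus-strand coding transcript, a 2-exon minus-strand coding
#' transcript, a miRNA transcript with a mature interval and one regulatory
#' feature; 10x reads of length 50 with PHRED 35 bases and planted
#' heterozygous SNPs carried on ~50% of overlapping reads; and a
#' 100-sample population genotyped at three variant pairs spanning strong
#' LD, moderate LD and linkage equilibrium.
#'
#' @param seed integer seed; all outputs derive from it.
#' @param genome_length reference length (bp).
#' @param seq_name reference sequence name.
#' @param read_len,depth,base_qual,error_rate,error_qual read profile.
#' @param planted_pos positions of planted heterozygous SNPs (NULL = pick
#'   CDS-interior positions automatically).
#' @param n_samples population size.
#' @param hap_blocks list of two-locus blocks, each
#'   \code{list(positions = c(p1, p2), freqs = c(AB, Ab, aB, ab))}.
#' @return list of class \code{fixture_spec}.
#' @export
fixture_spec <- function(seed = 1L, genome_length = 20000L,
                         seq_name = "chr1", read_len = 50L, depth = 10L,
                         base_qual = 35L, error_rate = 0, error_qual = 10L,
                         planted_pos = NULL, n_samples = 100L,
                         hap_blocks = NULL) {
  if (is.null(hap_blocks))
    hap_blocks <- list(
      list(positions = c(1000L, 1400L), freqs = c(0.5, 0, 0, 0.5)),
      list(positions = c(3000L, 3500L), freqs = c(0.45, 0.15, 0.15, 0.25)),
      list(positions = c(9000L, 9600L), freqs = c(0.25, 0.25, 0.25, 0.25)))
  for (b in hap_blocks)
    if (abs(sum(b$freqs) - 1) > 1e-12)
      stop("haplotype frequencies must sum to 1 in every block")
  structure(list(seed = as.integer(seed), genome_length = genome_length,
                 seq_name = seq_name, read_len = read_len, depth = depth,
                 base_qual = base_qual, error_rate = error_rate,
                 error_qual = error_qual, planted_pos = planted_pos,
                 n_samples = n_samples, hap_blocks = hap_blocks),
            class = "fixture_spec")
}

## Deterministic sub-seed per output stream, kept under 2^31.
sub_seed <- function(spec, stream) {
  (spec$seed * 97L + stream * 131L) %% 2000000011L
}

fixture_transcript_layout <- function(spec) {
  ## fixed layout relative to the reference: a 3-exon plus-strand coding
  ## transcript mid-sequence, a 2-exon minus-strand coding transcript,
  ## and a miRNA gene. Coordinates assume genome_length >= 18000.
  list(
    list(id = "TX1", gene_id = "G1", strand = 1L,
         exons = rbind(c(7000L, 7200L), c(7400L, 7700L), c(7950L, 8200L)),
         cds_start = 7100L, cds_end = 8100L, biotype = "protein_coding"),
    list(id = "TX2", gene_id = "G2", strand = -1L,
         exons = rbind(c(12000L, 12400L), c(12700L, 13100L)),
         cds_start = 12100L, cds_end = 13000L, biotype = "protein_coding"),
    list(id = "TX3", gene_id = "G3", strand = 1L,
         exons = rbind(c(15000L, 15120L)),
         cds_start = NA, cds_end = NA, biotype = "miRNA",
         mature_mirna = rbind(c(15040L, 15060L))))
}

#' Generate the reference genome, annotation and regulatory features
#'
#' Writes FASTA, GTF and BED files reproducible from the seed.
#'
#' @param spec a \code{fixture_spec}.
#' @param out_dir output directory (created if absent).
#' @return list: \code{genome}, \code{transcripts}, \code{regulatory}, and
#'   the file \code{paths}.
#' @export
make_genome_and_annotation <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(sub_seed(spec, 1L))
  bases <- sample(c("A", "C", "G", "T"), spec$genome_length, replace = TRUE)
  ## give TX1 a clean CDS frame: ATG...no internal premature stops are not
  ## required for the consequence rules, but avoid a reference stop at the
  ## very first codon so Stop lost is reachable at the true terminator
  seqs <- stats::setNames(paste(bases, collapse = ""), spec$seq_name)
  genome <- reference_genome(seqs)
  txs <- lapply(fixture_transcript_layout(spec), function(l)
    transcript_model(l$id, l$gene_id, spec$seq_name, l$strand, l$exons,
                     cds_start = l$cds_start %||% NA, cds_end = l$cds_end %||% NA,
                     biotype = l$biotype, mature_mirna = l$mature_mirna))
  names(txs) <- vapply(txs, `[[`, "", "id")
  ## force the CDS of TX1 and TX2 to end in a stop codon and to carry no
  ## premature stop, so stop gained/lost classes appear where expected
  genome <- ensure_clean_cds(genome, txs[["TX1"]])
  genome <- ensure_clean_cds(genome, txs[["TX2"]])
  regs <- regulatory_features(spec$seq_name, 17000L, 17200L, "G1")
  paths <- list(fasta = file.path(out_dir, "genome.fa"),
                gtf = file.path(out_dir, "annotation.gtf"),
                bed = file.path(out_dir, "regulatory.bed"))
  write_fasta(genome, paths$fasta)
  write_gtf(txs, paths$gtf)
  writeLines(paste(regs$seq_name, regs$start - 1L, regs$end, regs$linked_gene,
                   sep = "\t"), paths$bed)
  list(genome = genome, transcripts = txs, regulatory = regs, paths = paths)
}

## Rewrite the reference so the transcript's CDS has no internal stop codon
## and terminates with TAA.
ensure_clean_cds <- function(genome, t) {
  cds <- cds_sequence(t, genome)
  n_codon <- nchar(cds) %/% 3L
  aa <- strsplit(translate_dna(cds), NULL)[[1]]
  fix_codon <- function(i, codon) {
    for (k in 0:2) {
      gpos <- cds_to_genomic(t, 3L * (i - 1L) + 1L + k)
      b <- substr(codon, k + 1L, k + 1L)
      if (t$strand < 0L) b <- revcomp(b)
      s <- genome$sequences[[t$seq_name]]
      substr(s, gpos, gpos) <- b
      genome$sequences[[t$seq_name]] <<- s
    }
  }
  for (i in seq_len(n_codon - 1L)) if (aa[i] == "*") fix_codon(i, "TGG")
  fix_codon(n_codon, "TAA")
  reference_genome(genome$sequences)
}

#' Write transcript models as GTF
#'
#' @param txs named list of \code{transcript_model}s.
#' @param path output file.
#' @export
write_gtf <- function(txs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (t in txs) {
    strand <- if (t$strand > 0L) "+" else "-"
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; transcript_biotype "%s";',
                     t$gene_id, t$id, t$biotype)
    emit <- function(type, s, e)
      writeLines(paste(t$seq_name, "variantkit", type, s, e, ".", strand, ".",
                       attrs, sep = "\t"), con)
    for (i in seq_len(nrow(t$exons))) emit("exon", t$exons[i, 1], t$exons[i, 2])
    if (is_coding(t)) {
      for (i in seq_len(nrow(t$exons))) {
        s <- max(t$exons[i, 1], t$cds_start); e <- min(t$exons[i, 2], t$cds_end)
        if (s <= e) emit("CDS", s, e)
      }
    }
    if (!is.null(t$mature_mirna))
      for (i in seq_len(nrow(t$mature_mirna)))
        emit("mature_miRNA", t$mature_mirna[i, 1], t$mature_mirna[i, 2])
  }
  invisible(path)
}

#' Generate reads with planted heterozygous SNPs
#'
#' Reads tile the coding-transcript region at the spec's depth; at each
#' planted position, alternating overlapping reads carry the alternate
#' allele so roughly half the coverage supports each allele. Sequencing
#' errors (at \code{error_rate}, with PHRED \code{error_qual}) never touch
#' planted sites. A truth table of planted SNPs is written alongside.
#'
#' @param spec a \code{fixture_spec}.
#' @param genome the \code{reference_genome} from
#'   \code{\link{make_genome_and_annotation}}.
#' @param out_dir output directory.
#' @return list: \code{reads} (an \code{aligned_reads} table), \code{truth}
#'   (data.frame pos/ref/alt), and file \code{paths} (SAM, reads TSV, truth
#'   TSV).
#' @export
make_reads <- function(spec, genome, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(sub_seed(spec, 2L))
  region <- c(6500L, 8700L)  # covers TX1 and flanks
  planted <- spec$planted_pos %||% c(7150L, 7550L, 8000L, 7300L, 6800L)
  n_reads <- ceiling(spec$depth * (region[2] - region[1] + 1) / spec$read_len)
  starts <- sort(sample(region[1]:(region[2] - spec$read_len + 1L), n_reads,
                        replace = TRUE))
  refseq <- genome$sequences[[spec$seq_name]]
  seqs <- substring(refseq, starts, starts + spec$read_len - 1L)
  quals <- rep(int_to_phred(rep(spec$base_qual, spec$read_len)), n_reads)
  truth <- data.frame(seq_name = spec$seq_name, pos = planted,
                      ref = substring(refseq, planted, planted),
                      alt = NA_character_, stringsAsFactors = FALSE)
  other <- function(b) setdiff(c("A", "C", "G", "T"), b)[sample.int(3L, 1L)]
  truth$alt <- vapply(truth$ref, other, "")
  for (k in seq_len(nrow(truth))) {
    p <- truth$pos[k]
    covering <- which(starts <= p & starts + spec$read_len - 1L >= p)
    carrier <- covering[seq_along(covering) %% 2L == 1L]  # alternate reads
    for (ri in carrier) {
      off <- p - starts[ri] + 1L
      substr(seqs[ri], off, off) <- truth$alt[k]
    }
  }
  if (spec$error_rate > 0) {
    for (ri in seq_len(n_reads)) {
      errs <- which(stats::runif(spec$read_len) < spec$error_rate)
      errs <- errs[!(starts[ri] + errs - 1L) %in% truth$pos]
      for (off in errs) {
        substr(seqs[ri], off, off) <- other(substr(seqs[ri], off, off))
        q <- phred_to_int(quals[ri]); q[off] <- spec$error_qual
        quals[ri] <- int_to_phred(q)
      }
    }
  }
  reads <- aligned_reads(
    read_id = sprintf("read%05d", seq_len(n_reads)),
    seq_name = spec$seq_name, start = starts,
    cigar = paste0(spec$read_len, "M"), read_seq = seqs, quals = quals,
    mate_status = "properly_paired", individual = "IND1")
  paths <- list(sam = file.path(out_dir, "reads.sam"),
                tsv = file.path(out_dir, "reads.tsv"),
                truth = file.path(out_dir, "truth_snps.tsv"))
  write_sam(reads, paths$sam, genome)
  write_reads_tsv(reads, paths$tsv)
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(reads = reads, truth = truth, paths = paths)
}

#' Generate population genotypes from known haplotype frequencies
#'
#' Each two-locus block draws, per sample, two haplotypes from the block's
#' target frequencies (random union of gametes); the VCF records unphased
#' genotypes. A truth table of target frequencies and their implied r2/D'
#' is written alongside.
#'
#' @param spec a \code{fixture_spec}.
#' @param genome the fixture \code{reference_genome}.
#' @param out_dir output directory.
#' @return list: \code{gmat} (a \code{genotype_matrix}), \code{truth}
#'   (data.frame per block), and file \code{paths} (VCF, truth TSV,
#'   population file).
#' @export
make_genotypes <- function(spec, genome, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(sub_seed(spec, 3L))
  refseq <- genome$sequences[[spec$seq_name]]
  samples <- sprintf("S%03d", seq_len(spec$n_samples))
  vars <- list(); genos <- list(); truth <- list()
  for (bi in seq_along(spec$hap_blocks)) {
    b <- spec$hap_blocks[[bi]]
    p1 <- b$positions[1]; p2 <- b$positions[2]
    ref1 <- substring(refseq, p1, p1); ref2 <- substring(refseq, p2, p2)
    alt1 <- setdiff(c("A", "C", "G", "T"), ref1)[1]
    alt2 <- setdiff(c("A", "C", "G", "T"), ref2)[1]
    ## haplotypes coded (locus1, locus2) with 0 = ref: AB, Ab, aB, ab
    hap_alleles <- rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
    h1 <- sample.int(4L, spec$n_samples, replace = TRUE, prob = b$freqs)
    h2 <- sample.int(4L, spec$n_samples, replace = TRUE, prob = b$freqs)
    g1 <- hap_alleles[h1, 1L] + hap_alleles[h2, 1L]
    g2 <- hap_alleles[h1, 2L] + hap_alleles[h2, 2L]
    vars[[length(vars) + 1L]] <- data.frame(
      variant_id = sprintf("blk%d_snp1", bi), seq_name = spec$seq_name,
      pos = p1, allele_1 = ref1, allele_2 = alt1, stringsAsFactors = FALSE)
    vars[[length(vars) + 1L]] <- data.frame(
      variant_id = sprintf("blk%d_snp2", bi), seq_name = spec$seq_name,
      pos = p2, allele_1 = ref2, allele_2 = alt2, stringsAsFactors = FALSE)
    genos[[length(genos) + 1L]] <- g1
    genos[[length(genos) + 1L]] <- g2
    s <- ld_stats(b$freqs)
    truth[[bi]] <- data.frame(block = bi, id1 = sprintf("blk%d_snp1", bi),
                              id2 = sprintf("blk%d_snp2", bi),
                              p_AB = b$freqs[1], p_Ab = b$freqs[2],
                              p_aB = b$freqs[3], p_ab = b$freqs[4],
                              true_D = s$D, true_d_prime = abs(s$d_prime),
                              true_r2 = ifelse(is.na(s$r2), NA, s$r2))
  }
  vdf <- do.call(rbind, vars)
  geno <- do.call(rbind, genos)
  ord <- order(vdf$seq_name, vdf$pos)
  vdf <- vdf[ord, , drop = FALSE]; geno <- geno[ord, , drop = FALSE]
  gmat <- genotype_matrix("POP1", samples, vdf, geno)
  truth <- do.call(rbind, truth)
  ## VCF output
  v <- variant_records(vdf$seq_name, vdf$pos, vdf$pos, vdf$allele_1,
                       as.list(vdf$allele_2), id = vdf$variant_id)
  gts <- matrix(c("0/0", "0/1", "1/1")[geno + 1L], nrow = nrow(geno),
                dimnames = list(vdf$variant_id, samples))
  paths <- list(vcf = file.path(out_dir, "genotypes.vcf"),
                truth = file.path(out_dir, "truth_ld.tsv"),
                population = file.path(out_dir, "population.txt"))
  write_vcf(v, paths$vcf, gt = gts)
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(samples, paths$population)
  list(gmat = gmat, truth = truth, paths = paths)
}

#' Generate the full fixture bundle
#'
#' Reference + annotation, reads with planted SNPs, and population
#' genotypes, all reproducible from the spec's seed.
#'
#' @param spec a \code{fixture_spec}.
#' @param out_dir output directory.
#' @return list combining the three generators' outputs.
#' @export
simulate_bundle <- function(spec, out_dir) {
  ga <- make_genome_and_annotation(spec, out_dir)
  rd <- make_reads(spec, ga$genome, out_dir)
  gt <- make_genotypes(spec, ga$genome, out_dir)
  list(genome = ga$genome, transcripts = ga$transcripts,
       regulatory = ga$regulatory, reads = rd$reads,
       snp_truth = rd$truth, gmat = gt$gmat, ld_truth = gt$truth,
       paths = c(ga$paths, rd$paths, gt$paths))
}
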