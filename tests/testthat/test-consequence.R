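genome <- tiny_genome()
tp <- tiny_tx_plus()    # exons 41-100, 121-200, 241-300; CDS 61-280
tm <- tiny_tx_minus()

## single-SNV annotation against one transcript
one <- function(pos, alt, t = tp, g = genome)
  classify_variant("v", pos, pos, ref_seq(g, t$seq_name, pos, pos), alt, t, g)

test_that("severity vocabulary is a closed total order", {
  ct <- consequence_types()
  expect_equal(length(ct), 26L)
  expect_equal(anyDuplicated(ct), 0L)
  expect_equal(consequence_rank("Stop gained"), 1L)
  expect_equal(consequence_rank("Intergenic"), 26L)
  expect_error(consequence_rank("Missense"), "unknown")
})

test_that("coding SNVs classify by codon translation", {
  # force a known codon: find a CDS position and construct the needed genome
  g2 <- genome
  # place TGG (Trp) at CDS codon 5 (cds positions 13-15)
  for (k in 0:2) {
    gp <- cds_to_genomic(tp, 13L + k)
    substr(g2$sequences[["chrT"]], gp, gp) <- substr("TGG", k + 1L, k + 1L)
  }
  g2 <- reference_genome(g2$sequences)
  p3 <- cds_to_genomic(tp, 15L)  # third base of the TGG codon
  expect_equal(one(p3, "A", g = g2)$consequence_type, "Stop gained")  # TGG->TGA
  expect_equal(one(p3, "C", g = g2)$consequence_type,
               "Non-synonymous coding")                               # TGG->TGC Trp->Cys
})

test_that("stop lost, synonymous and non-synonymous are detected", {
  g2 <- genome
  # terminal codon TAA at the last CDS codon
  n <- cds_length(tp) %/% 3L
  for (k in 0:2) {
    gp <- cds_to_genomic(tp, 3L * (n - 1L) + 1L + k)
    substr(g2$sequences[["chrT"]], gp, gp) <- substr("TAA", k + 1L, k + 1L)
  }
  # CTG (Leu) at codon 10
  for (k in 0:2) {
    gp <- cds_to_genomic(tp, 28L + k)
    substr(g2$sequences[["chrT"]], gp, gp) <- substr("CTG", k + 1L, k + 1L)
  }
  g2 <- reference_genome(g2$sequences)
  stop2 <- cds_to_genomic(tp, 3L * (n - 1L) + 2L)
  expect_equal(one(stop2, "C", g = g2)$consequence_type, "Stop lost")  # TAA->TCA
  leu3 <- cds_to_genomic(tp, 30L)
  expect_equal(one(leu3, "A", g = g2)$consequence_type,
               "Synonymous coding")                                    # CTG->CTA both Leu
  leu1 <- cds_to_genomic(tp, 28L)
  expect_equal(one(leu1, "G", g = g2)$consequence_type,
               "Non-synonymous coding")                                # CTG->GTG Leu->Val
  # coding detail fields are populated
  call <- one(leu3, "A", g = g2)
  expect_equal(call$cds_pos, 30L)
  expect_equal(call$protein_pos, 10L)
  expect_equal(call$ref_codon, "CTG"); expect_equal(call$alt_codon, "CTA")
})

test_that("splice-site positional rules flip at the documented offsets", {
  # intron 1 of tp: 101-120; intron 2: 201-240
  expect_equal(one(101L, other <- setdiff(c("A","C","G","T"),
                   ref_seq(genome,"chrT",101L,101L))[1])$consequence_type,
               "Essential splice site, intronic")
  expect_equal(one(102L, "A")$consequence_type[1] %in%
                 "Essential splice site, intronic", TRUE)
  lab <- function(pos) {
    alt <- setdiff(c("A", "C", "G", "T"), ref_seq(genome, "chrT", pos, pos))[1]
    one(pos, alt)$consequence_type
  }
  expect_equal(lab(103L), "Splice site, intronic")      # offset 3
  expect_equal(lab(108L), "Splice site, intronic")      # offset 8
  expect_equal(lab(109L), "Intronic")                   # offset 9
  expect_equal(lab(112L), "Intronic")
  expect_equal(lab(119L), "Essential splice site, intronic")  # 2 from 3' edge
  # exon-edge modifier: 1-3 bp into exon 2 (CDS): splice-site coding classes
  e2 <- lab(121L)
  expect_true(grepl("splice site|Splice site", e2))
  expect_true(grepl("coding", e2))
  e4 <- lab(124L)
  expect_false(grepl("splice", e4, ignore.case = TRUE))  # offset 4: modifier dropped
  # UTR bases 1-3 bp into an exon get the UTR splice-modifier labels:
  # 5' UTR runs to 129 just after the splice junction at 121
  t5 <- transcript_model("U5", "G", "chrT", 1L,
                         rbind(c(41L, 100L), c(121L, 200L)),
                         cds_start = 130L, cds_end = 190L)
  # 3' UTR 96-100 ends 1 bp before the splice junction at 100
  t3 <- transcript_model("U3", "G", "chrT", 1L,
                         rbind(c(41L, 100L), c(121L, 200L)),
                         cds_start = 50L, cds_end = 95L)
  lab_t <- function(pos, t) {
    alt <- setdiff(c("A", "C", "G", "T"), ref_seq(genome, "chrT", pos, pos))[1]
    classify_variant("v", pos, pos, ref_seq(genome, "chrT", pos, pos),
                     alt, t, genome)$consequence_type
  }
  expect_equal(lab_t(121L, t5), "Splice site, 5' UTR")  # 1 bp into the exon
  expect_equal(lab_t(123L, t5), "Splice site, 5' UTR")  # 3 bp
  expect_equal(lab_t(124L, t5), "5' UTR")               # 4 bp: modifier dropped
  expect_equal(lab_t(100L, t3), "Splice site, 3' UTR")
  expect_equal(lab_t(96L, t3), "3' UTR")                # 5 bp from the junction
})

test_that("upstream/downstream are transcript-oriented and bounded at 5 kb", {
  big <- reference_genome(c(chrT = strrep("ACGT", 4000)))  # 16 kb
  t_plus <- transcript_model("P", "G", "chrT", 1L, rbind(c(7000L, 7299L)),
                             cds_start = 7060L, cds_end = 7250L)
  t_minus <- transcript_model("M", "G", "chrT", -1L, rbind(c(7000L, 7299L)),
                              cds_start = 7060L, cds_end = 7250L)
  cls <- function(pos, t) classify_variant("v", pos, pos,
                                           ref_seq(big, "chrT", pos, pos),
                                           "A", t, big)$consequence_type
  expect_equal(cls(2000L, t_plus), "Upstream")     # 5000 bp away
  expect_equal(length(classify_variant("v", 1999L, 1999L, "N", "A", t_plus, big)$consequence_type), 0L)
  expect_equal(cls(12299L, t_plus), "Downstream")  # 5000 bp downstream
  expect_equal(cls(2000L, t_minus), "Downstream")  # left of a minus-strand tx
  expect_equal(cls(12299L, t_minus), "Upstream")
  # scope helper agrees, and an empty scope means intergenic
  sc <- transcripts_in_scope("chrT", 1999L, 1999L, list(t_plus))
  expect_equal(length(sc$transcripts), 0L)
  ann <- annotate_variants(
    variant_records("chrT", 1999L, 1999L, ref_seq(big, "chrT", 1999L, 1999L),
                    list("A"), id = "iv"),
    list(t_plus), big)
  expect_equal(ann$consequence_type, "Intergenic")
})

test_that("indels follow frameshift / in-frame / border rules", {
  del <- function(start, end)   # deletion of [start,end]
    classify_variant("v", start, end, ref_seq(genome, "chrT", start, end),
                     "-", tp, genome)
  # 2 bp deletion wholly inside CDS -> frameshift
  expect_equal(del(130L, 131L)$consequence_type, "Frameshift coding")
  # 3 bp deletion wholly inside CDS -> in-frame, no frameshift label
  expect_equal(del(130L, 132L)$consequence_type, "Non-synonymous coding")
  # deletion spanning the exon/intron border -> complex indel
  expect_equal(del(199L, 203L)$consequence_type, "Complex InDel")
  # deletion spanning the CDS/5'UTR border (UTR 41-60, CDS from 61)
  expect_equal(del(59L, 62L)$consequence_type, "Complex InDel")
  # insertion in CDS: 1 bp -> frameshift; 3 bp -> in-frame
  ins <- function(pos, alt) classify_variant("v", pos + 1L, pos, "-", alt,
                                             tp, genome)
  expect_equal(ins(130L, "G")$consequence_type, "Frameshift coding")
  expect_equal(ins(130L, "GAT")$consequence_type, "Non-synonymous coding")
  # intronic deletion away from splice sites stays intronic
  expect_equal(del(110L, 111L)$consequence_type, "Intronic")
  # deletion of an essential splice base
  expect_equal(del(101L, 102L)$consequence_type,
               "Essential splice site, intronic")
})

test_that("multi-allelic stop-gain + frameshift collapses to the combined class", {
  g2 <- genome
  for (k in 0:2) {
    gp <- cds_to_genomic(tp, 13L + k)
    substr(g2$sequences[["chrT"]], gp, gp) <- substr("TGG", k + 1L, k + 1L)
  }
  g2 <- reference_genome(g2$sequences)
  p3 <- cds_to_genomic(tp, 15L)
  # alleles: A (TGG->TGA stop) and a 1 bp deletion-like alt via "-"? use
  # an insertion-style alt on the same record instead: G/"GA" (length 2)
  calls <- classify_variant("v", p3, p3, ref_seq(g2, "chrT", p3, p3),
                            c("A", paste0(ref_seq(g2, "chrT", p3, p3), "A")),
                            tp, g2)
  expect_true("Stop gained, frameshift coding" %in% calls$consequence_type)
  expect_false(any(calls$consequence_type %in% c("Stop gained",
                                                 "Frameshift coding")))
})

test_that("non-coding, miRNA, regulatory and ranking behave as specified", {
  mir <- transcript_model("MIR", "GM", "chrT", 1L, rbind(c(320L, 380L)),
                          biotype = "miRNA",
                          mature_mirna = rbind(c(340L, 360L)))
  lab <- function(pos) classify_variant("v", pos, pos,
                                        ref_seq(genome, "chrT", pos, pos),
                                        "A", mir, genome)$consequence_type
  expect_equal(lab(350L), "Within mature miRNA")
  expect_equal(lab(325L), "Within non-coding gene")
  regs <- regulatory_features("chrT", 105L, 118L, "GP")
  v <- variant_records("chrT", 112L, 112L,
                       ref_seq(genome, "chrT", 112L, 112L),
                       list(setdiff(c("A","C","G","T"),
                                    ref_seq(genome, "chrT", 112L, 112L))[1]),
                       id = "rv")
  ann <- annotate_variants(v, list(tp), genome, regs)
  expect_true("Regulatory region" %in% ann$consequence_type)
  expect_true("Intronic" %in% ann$consequence_type)
  # ranking: most severe first, ties by transcript id
  mixed <- rbind(consequence_call("v", "TB", "Intronic"),
                 consequence_call("v", "TA", "Intronic"),
                 consequence_call("v", "TZ", "Stop gained"))
  r <- rank_calls(mixed)
  expect_equal(r$consequence_type[1], "Stop gained")
  expect_equal(r$transcript_id[2:3], c("TA", "TB"))
})

test_that("per-base sweep matches the independent brute-force classifier", {
  ## every base across the transcript span plus 30 bp flanks, one alt each
  for (t in list(tp, tm)) {
    for (pos in (tx_start(t) - 30L):(tx_end(t) + 30L)) {
      ref <- ref_seq(genome, "chrT", pos, pos)
      alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
      got <- classify_variant("v", pos, pos, ref, alt, t, genome)
      want <- oracle_classify_snv(pos, alt, t, genome)
      expect_equal(got$consequence_type, want,
                   info = paste(t$id, "pos", pos))
    }
  }
})
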