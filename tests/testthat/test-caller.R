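cg <- tiny_genome()

## read factory: perfect-match read with selective base/quality edits
## subs: list of list(off = read offset 1-based, base = new base or NULL,
## qual = new qual or NULL)
clean_read <- function(id, start, len = 21L, ind = "A", subs = list(),
                       mate = "properly_paired", q0 = 35L) {
  s <- ref_seq(cg, "chrT", start, start + len - 1L)
  q <- rep(q0, len)
  for (sb in subs) {
    if (!is.null(sb$base)) substr(s, sb$off, sb$off) <- sb$base
    if (!is.null(sb$qual)) q[sb$off] <- sb$qual
  }
  aligned_reads(id, "chrT", start, paste0(len, "M"), s, int_to_phred(q),
                mate, ind)
}

cat_reads <- function(...) {
  r <- do.call(rbind, lapply(list(...), as.data.frame))
  r$read_id <- sprintf("%s_%04d", r$read_id, seq_len(nrow(r)))
  class(r) <- c("aligned_reads", "data.frame")
  r
}

other_base <- function(pos) setdiff(c("A", "C", "G", "T"),
                                    ref_seq(cg, "chrT", pos, pos))[1]

test_that("nqs_pass enforces variant quality, exact flanks, and the mismatch window", {
  pos <- 100L; alt <- other_base(pos)
  base_read <- function(vq = 23L, subs = list())
    clean_read("r", pos - 10L, subs = c(list(list(off = 11L, base = alt, qual = vq)),
                                        subs))
  # variant base Q=23, flanks Q=35 matches -> pass; Q=22 -> fail
  expect_true(nqs_pass(base_read(23L), 10L, genome = cg))
  expect_false(nqs_pass(base_read(22L), 10L, genome = cg))
  # flank base qualities: > 15 required (16 passes, 15 fails)
  r <- base_read(23L, subs = lapply(c(6:10, 12:16), function(o) list(off = o, qual = 16L)))
  expect_true(nqs_pass(r, 10L, genome = cg))
  r <- base_read(23L, subs = list(list(off = 8L, qual = 15L)))
  expect_false(nqs_pass(r, 10L, genome = cg))
  # a mismatch inside the exact +-5 flank fails
  r <- base_read(23L, subs = list(list(off = 8L, base = other_base(pos - 3L))))
  expect_false(nqs_pass(r, 10L, genome = cg))
  # one mismatch in the +-10 window beyond the flank is tolerated, two are not
  r1 <- base_read(23L, subs = list(list(off = 18L, base = other_base(pos + 7L), qual = 22L)))
  expect_true(nqs_pass(r1, 10L, genome = cg))
  r2 <- base_read(23L, subs = list(list(off = 18L, base = other_base(pos + 7L), qual = 22L),
                                   list(off = 4L, base = other_base(pos - 7L), qual = 22L)))
  expect_false(nqs_pass(r2, 10L, genome = cg))
  # too near the read end: insufficient flank is FALSE, not an error
  r <- clean_read("e", pos, subs = list(list(off = 3L, base = other_base(pos + 2L))))
  expect_false(nqs_pass(r, 2L, genome = cg))
  # a gap in the flank (deletion) breaks the exact-alignment requirement
  gap <- aligned_reads("d", "chrT", pos - 10L, "8M2D13M",
                       paste0(ref_seq(cg, "chrT", pos - 10L, pos - 3L),
                              ref_seq(cg, "chrT", pos, pos + 12L)),
                       int_to_phred(rep(35L, 21L)), "unpaired", "A")
  # variant offset 10 (0-based) sits right of the deletion
  expect_false(nqs_pass(gap, 10L, genome = cg))
})

test_that("call_snps applies depth, allele-count and minor-allele rules", {
  pos <- 150L; alt <- other_base(pos)
  alt_read <- function(id, ind = "A")
    clean_read(id, pos - 10L, ind = ind,
               subs = list(list(off = 11L, base = alt)))
  ref_read <- function(id, ind = "A") clean_read(id, pos - 10L, ind = ind)
  # 3 alt + 2 ref -> het call with counts {ref:2, alt:3}
  reads <- cat_reads(alt_read("a1"), alt_read("a2"), alt_read("a3"),
                     ref_read("b1"), ref_read("b2"))
  calls <- call_snps(reads, cg)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$pos, pos)
  expect_equal(calls$alt_alleles[[1]], alt)
  cnt <- calls$counts[[1]]
  expect_equal(unname(cnt[alt]), 3L)
  expect_equal(unname(cnt[ref_seq(cg, "chrT", pos, pos)]), 2L)
  # minor allele on a single read at depth >= 4 -> no call
  reads1 <- cat_reads(alt_read("a1"), ref_read("b1"), ref_read("b2"),
                      ref_read("b3"))
  expect_equal(nrow(call_snps(reads1, cg)), 0L)
  # ...but at depth 3 ("coverage of greater than 3" not met) a single
  # alt read suffices
  reads2 <- cat_reads(alt_read("a1"), ref_read("b1"), ref_read("b2"))
  expect_equal(nrow(call_snps(reads2, cg)), 1L)
  # three distinct alleles for one individual -> site discarded
  alt2 <- setdiff(c("A", "C", "G", "T"),
                  c(ref_seq(cg, "chrT", pos, pos), alt))[1]
  reads3 <- cat_reads(alt_read("a1"), alt_read("a2"),
                      clean_read("c", pos - 10L,
                                 subs = list(list(off = 11L, base = alt2))),
                      clean_read("c2", pos - 10L,
                                 subs = list(list(off = 11L, base = alt2))),
                      ref_read("b1"), ref_read("b2"))
  expect_equal(nrow(call_snps(reads3, cg)), 0L)
  # improperly paired reads are excluded from evidence
  reads4 <- cat_reads(alt_read("a1"), alt_read("a2"))
  reads4$mate_status <- "improperly_paired"
  expect_equal(nrow(call_snps(reads4, cg)), 0L)
  # unknown sequence name is a coordinate error
  bad <- alt_read("x"); bad$seq_name <- "chrZ"
  expect_error(call_snps(bad, cg), "unknown sequence")
})

test_that("site depth boundary: 100 aligned reads allowed, 101 not", {
  pos <- 200L; alt <- other_base(pos)
  mk <- function(n) {
    reads <- do.call(cat_reads, lapply(seq_len(n), function(i)
      clean_read(paste0("r", i), pos - 10L,
                 subs = if (i %% 2L == 1L) list(list(off = 11L, base = alt))
                        else list())))
    reads
  }
  expect_equal(nrow(call_snps(mk(100L), cg)), 1L)
  expect_equal(nrow(call_snps(mk(101L), cg)), 0L)
})

test_that("read mismatch boundary: 30 mismatches kept, 31 dropped", {
  pos <- 200L; alt <- other_base(pos)
  # 120 bp read, variant at offset 60; extra low-quality mismatches spaced
  # 12 bp apart outside the variant's +-10 window
  mk_long <- function(n_extra, id) {
    offs <- setdiff(seq(2L, 120L, by = 2L), 48:72)[seq_len(n_extra)]
    subs <- c(list(list(off = 60L, base = alt)),
              lapply(offs, function(o)
                list(off = o, base = other_base(pos - 60L + o), qual = 10L)))
    clean_read(id, pos - 59L, len = 120L, subs = subs)
  }
  support <- cat_reads(mk_long(29L, "v1"), mk_long(29L, "v2"),
                       clean_read("b1", pos - 10L), clean_read("b2", pos - 10L))
  calls <- call_snps(support, cg)   # 29 + variant = 30 mismatches: kept
  expect_equal(nrow(calls), 1L)
  support31 <- cat_reads(mk_long(30L, "v1"), mk_long(30L, "v2"),
                         clean_read("b1", pos - 10L), clean_read("b2", pos - 10L))
  expect_equal(nrow(call_snps(support31, cg)), 0L)  # 31 mismatches: dropped
})

test_that("caps shrink under low genome coverage", {
  pos <- 200L; alt <- other_base(pos)
  reads <- do.call(cat_reads, lapply(1:60, function(i)
    clean_read(paste0("r", i), pos - 10L,
               subs = if (i %% 2L == 1L) list(list(off = 11L, base = alt))
                      else list())))
  expect_equal(nrow(call_snps(reads, cg, genome_coverage = 1)), 1L)
  # at < 0.1x the site-depth cap halves to 50, so 60 reads is too deep
  expect_equal(nrow(call_snps(reads, cg, genome_coverage = 0.05)), 0L)
})

test_that("calls are monotone in the variant-quality threshold and order-invariant", {
  set.seed(11)
  spec <- fixture_spec(seed = 5L)
  b <- simulate_bundle(spec, file.path(tempdir(), "calmono"))
  reads <- b$reads
  cfgs <- lapply(c(20L, 23L, 30L, 36L), function(q)
    caller_config(min_variant_phred = q))
  ns <- vapply(cfgs, function(cfg) nrow(call_snps(reads, b$genome, cfg)), 1L)
  expect_true(all(diff(ns) <= 0))
  # raising the threshold never adds a site
  sites <- lapply(cfgs, function(cfg) call_snps(reads, b$genome, cfg)$pos)
  for (k in seq_len(length(sites) - 1L))
    expect_true(all(sites[[k + 1L]] %in% sites[[k]]))
  # permuting read order leaves the calls unchanged
  perm <- reads[sample.int(nrow(reads)), , drop = FALSE]
  class(perm) <- c("aligned_reads", "data.frame")
  c1 <- call_snps(reads, b$genome); c2 <- call_snps(perm, b$genome)
  rownames(c1) <- rownames(c2) <- NULL
  expect_equal(c1, c2)
})

test_that("caller matches the literal-rule brute-force oracle on small read sets", {
  for (seed in 1:3) {
    set.seed(seed)
    # random 40-50 read fixture around pos 120-280 with assorted edits
    n <- sample(40:50, 1)
    reads <- do.call(cat_reads, lapply(seq_len(n), function(i) {
      start <- sample(100:250, 1)
      subs <- list()
      if (runif(1) < 0.6) {
        off <- sample(6:16, 1)
        subs <- c(subs, list(list(off = off,
                                  base = other_base(start + off - 1L),
                                  qual = sample(c(10L, 22L, 23L, 35L), 1))))
      }
      if (runif(1) < 0.3) {
        off2 <- sample(1:21, 1)
        subs <- c(subs, list(list(off = off2, qual = sample(c(12L, 15L, 16L), 1))))
      }
      clean_read(paste0("s", i), start, subs = subs,
                 mate = sample(c("properly_paired", "improperly_paired",
                                 "unpaired"), 1))
    }))
    got <- call_snps(reads, cg)
    want <- oracle_call_snps(reads, cg)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0L) {
      expect_equal(got$pos, want$pos)
      expect_equal(got$individual, want$individual)
      got_alleles <- vapply(seq_len(nrow(got)), function(i)
        paste(sort(names(got$counts[[i]])), collapse = "/"), "")
      expect_equal(got_alleles, want$alleles)
    }
  }
})

test_that("SARA genotyping asserts reference-only evidence at known loci", {
  pos <- 250L; ref <- ref_seq(cg, "chrT", pos, pos); alt <- other_base(pos)
  known <- variant_records("chrT", pos, pos, ref, list(alt), id = "rs77")
  ref_read <- function(id) clean_read(id, pos - 10L)
  # 4 passing reference reads -> SARA call
  reads <- cat_reads(ref_read("r1"), ref_read("r2"), ref_read("r3"),
                     ref_read("r4"))
  s <- sara_genotype(reads, known, cg)
  expect_equal(nrow(s), 1L)
  expect_true(s$sara)
  expect_equal(unname(s$counts[[1]][ref]), 4L)
  expect_equal(length(s$alt_alleles[[1]]), 0L)
  # no passing reads (all low quality) -> no record
  low <- cat_reads(clean_read("l1", pos - 10L, q0 = 20L))
  expect_equal(nrow(sara_genotype(low, known, cg)), 0L)
  # any passing non-reference observation -> not SARA
  mixed <- cat_reads(ref_read("r1"), ref_read("r2"), ref_read("r3"),
                     clean_read("a", pos - 10L,
                                subs = list(list(off = 11L, base = alt))))
  expect_equal(nrow(sara_genotype(mixed, known, cg)), 0L)
})
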