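# The tiny_world plus-strand gene gp translates M W Q L K P *:
# codons ATG TGG CAG CTG AAA CCC TAA at chr1:11..31.

test_that("call_consequence classifies canonical EMS changes", {
  w <- tiny_world()
  gp <- w$models$gp
  v <- function(pos, ref, alt) list(chrom = "chr1", pos = pos,
                                    ref = ref, alt = alt)
  # TGG -> TAG (Trp -> stop), G>A at codon 2 position 2
  expect_equal(call_consequence(v(15, "G", "A"), gp, w$genome), "PTC")
  # CAG -> TAG (Gln -> stop), C>T at codon 3 position 1
  expect_equal(call_consequence(v(17, "C", "T"), gp, w$genome), "PTC")
  # CTG -> CTA (Leu -> Leu)
  expect_equal(call_consequence(v(22, "G", "A"), gp, w$genome), "synonymous")
  # AAA -> AGA (Lys -> Arg)
  expect_equal(call_consequence(v(24, "A", "G"), gp, w$genome), "missense")
  # TAA -> TGA: a different stop is "other", not synonymous
  expect_equal(call_consequence(v(30, "A", "G"), gp, w$genome), "other")
  # ATG -> ATA: start loss
  expect_equal(call_consequence(v(13, "G", "A"), gp, w$genome), "other")
  # outside the CDS
  expect_equal(call_consequence(v(5, "A", "G"), gp, w$genome), "non_coding")
})

test_that("call_consequence resolves minus-strand variants on the coding strand", {
  w <- tiny_world()
  gm <- w$models$gm
  # codon 2 position 2 of the minus-strand gene: CDS position 5
  gpos <- homoeocomp:::cds_to_genomic(gm, 5L)
  # coding-strand G>A appears as C>T on the forward strand
  expect_equal(call_consequence(list(chrom = "chr2", pos = gpos,
                                     ref = "C", alt = "T"), gm, w$genome),
               "PTC")
})

test_that("out-of-frame models and ref mismatches are rejected", {
  w <- tiny_world()
  bad <- gene_model("gbad", "chr1", "+", data.frame(start = 11, end = 30))
  expect_false(bad$frame_ok)
  expect_error(call_consequence(list(chrom = "chr1", pos = 15, ref = "G",
                                     alt = "A"), bad, w$genome),
               "divisible by 3")
  expect_error(call_consequence(list(chrom = "chr1", pos = 15, ref = "C",
                                     alt = "A"), w$models$gp, w$genome),
               "mismatch")
})

test_that("consequence caller agrees with full-CDS translation on random SNVs", {
  set.seed(99)
  n_checked <- 0
  while (n_checked < 1000) {
    wld <- random_gene_world()
    m <- wld$model
    chrom <- as.character(wld$genome[[1]])
    span <- c(min(m$cds$start) - 10, max(m$cds$end) + 10)
    for (i in 1:25) {
      pos <- sample(span[1]:span[2], 1)
      ref <- substr(chrom, pos, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      v <- list(chrom = "chrT", pos = pos, ref = ref, alt = alt)
      expect_identical(call_consequence(v, m, wld$genome),
                       oracle_consequence(v, m, wld$genome),
                       label = sprintf("SNV %s>%s at %d (%s strand)",
                                       ref, alt, pos, m$strand))
      n_checked <- n_checked + 1
    }
  }
})

make_variant_table <- function(rows) {
  df <- do.call(rbind, lapply(rows, as.data.frame))
  attr(df, "samples") <- setdiff(names(df),
                                 c("chrom", "pos", "ref", "alt", "csq"))
  df
}

test_that("filter_mutations applies the full cascade", {
  w <- tiny_world()
  groups <- homoeolog_groups("g1", "gp", "gm", NA)
  vt <- make_variant_table(list(
    # retained: PTC, hom in mutant, ref in WT, gene in a group
    list(chrom = "chr1", pos = 15, ref = "G", alt = "A",
         csq = NA_character_, WT = "0/0", M1 = "1/1"),
    # removed: heterozygous in the mutant
    list(chrom = "chr1", pos = 17, ref = "C", alt = "T",
         csq = NA_character_, WT = "0/0", M1 = "0/1"),
    # removed: shared with WT (cultivar SNP)
    list(chrom = "chr1", pos = 22, ref = "G", alt = "A",
         csq = NA_character_, WT = "1/1", M1 = "1/1"),
    # removed: missense
    list(chrom = "chr1", pos = 24, ref = "A", alt = "G",
         csq = NA_character_, WT = "0/0", M1 = "1/1"),
    # removed: outside any CDS
    list(chrom = "chr1", pos = 2, ref = "A", alt = "G",
         csq = NA_character_, WT = "0/0", M1 = "1/1")))
  asn <- filter_mutations(vt, groups, w$models, genome = w$genome)
  expect_equal(nrow(asn), 1)
  expect_equal(asn$gene_id, "gp")
  expect_equal(asn$consequence, "PTC")
  expect_equal(asn$group_id, "g1")
  expect_equal(asn$subgenome, "A")
  expect_equal(asn$cds_pos, 5L)
  counts <- attr(asn, "filter_counts")
  # each stage of the cascade only removes records
  expect_true(all(diff(unname(counts)) <= 0))
})

test_that("gene outside any homoeolog group is filtered out", {
  w <- tiny_world()
  groups <- homoeolog_groups("g1", "gp", "other_gene", NA)
  vt <- make_variant_table(list(
    list(chrom = "chr2", pos = homoeocomp:::cds_to_genomic(w$models$gm, 5L),
         ref = "C", alt = "T", csq = NA_character_, WT = "0/0", M1 = "1/1")))
  asn <- filter_mutations(vt, groups, w$models, genome = w$genome)
  expect_equal(nrow(asn), 0)
})

test_that("missing WT genotype errors by default and can be dropped", {
  w <- tiny_world()
  groups <- homoeolog_groups("g1", "gp", "gm", NA)
  vt <- make_variant_table(list(
    list(chrom = "chr1", pos = 15, ref = "G", alt = "A",
         csq = NA_character_, WT = "./.", M1 = "1/1")))
  expect_error(filter_mutations(vt, groups, w$models, genome = w$genome),
               "wild-type genotype")
  asn <- filter_mutations(vt, groups, w$models, genome = w$genome,
                          on_missing_wt = "drop")
  expect_equal(nrow(asn), 0)
})

test_that("INFO-annotated consequences are honoured when requested", {
  w <- tiny_world()
  groups <- homoeolog_groups("g1", "gp", "gm", NA)
  vt <- make_variant_table(list(
    # annotation says stop_gained; no genome needed in info mode
    list(chrom = "chr1", pos = 15, ref = "G", alt = "A",
         csq = "stop_gained", WT = "0/0", M1 = "1/1"),
    list(chrom = "chr1", pos = 22, ref = "G", alt = "A",
         csq = "missense_variant", WT = "0/0", M1 = "1/1")))
  asn <- filter_mutations(vt, groups, w$models, annotation = "info")
  expect_equal(asn$consequence, "PTC")
  # internal calling disagrees with the (wrong) annotation on purpose: the
  # "missense" record is really synonymous, qualifies, and then collapses
  # with the PTC under the one-assignment-per-(line, gene) rule
  asn2 <- filter_mutations(vt, groups, w$models, genome = w$genome,
                           annotation = "internal")
  expect_equal(asn2$consequence, "PTC")
  expect_equal(nrow(asn2), 1)
  # on separate genes both survive internal calling
  vt2 <- vt
  vt2$chrom[2] <- "chr2"
  vt2$pos[2] <- homoeocomp:::cds_to_genomic(w$models$gm, 12L)
  vt2$ref[2] <- "C"; vt2$alt[2] <- "T"   # coding-strand G>A on minus strand
  asn3 <- filter_mutations(vt2, groups, w$models, genome = w$genome,
                           annotation = "internal")
  expect_setequal(asn3$consequence, c("PTC", "synonymous"))
})

test_that("assign_groups enforces the one-mutated-homoeolog rule", {
  base <- data.frame(
    line = c("L1", "L1", "L1", "L2", "L1", "L1"),
    gene_id = c("a1", "b1", "b2", "a1", "a3", "b3"),
    group_id = c("g1", "g2", "g2", "g1", "g3", "g3"),
    subgenome = c("A", "A", "B", "A", "A", "B"),
    consequence = c("PTC", "PTC", "PTC", "PTC", "PTC", "synonymous"),
    cds_pos = 5L, chrom = "c", pos = 1L, stringsAsFactors = FALSE)
  ctx <- assign_groups(base)
  # g1 analyzable in both lines: two contexts, one unique group
  expect_equal(sum(ctx$group_id == "g1"), 2)
  expect_setequal(ctx$line[ctx$group_id == "g1"], c("L1", "L2"))
  # g2: two PTC homoeologs in the same line -> excluded
  expect_false("g2" %in% ctx$group_id)
  # g3: PTC + synonymous in different homoeologs -> excluded from both
  # classes (PTC precedence keeps it out of the synonymous set)
  expect_false("g3" %in% ctx$group_id)
  excl <- attr(ctx, "excluded")
  expect_setequal(excl$group_id, c("g2", "g3"))
})

test_that("VCF writing and reading round-trips genotypes and annotations", {
  w <- tiny_world()
  vt <- make_variant_table(list(
    list(chrom = "chr1", pos = 15, ref = "G", alt = "A",
         csq = "stop_gained", WT = "0/0", M1 = "1/1"),
    list(chrom = "chr2", pos = 9, ref = "T", alt = "C",
         csq = NA_character_, WT = "0/0", M1 = "0/1")))
  tmp <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(vt, tmp, contigs = c(chr1 = 41, chr2 = 36))
  back <- read_vcf(tmp)
  expect_equal(back$chrom, vt$chrom)
  expect_equal(back$pos, vt$pos)
  expect_equal(back$csq, vt$csq)
  expect_equal(back$WT, vt$WT)
  expect_equal(back$M1, vt$M1)
})

test_that("read_vcf splits multi-allelic sites and normalises genotypes", {
  tmp <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##contig=<ID=chr1,length=100>",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "WT", "M1", sep = "\t"),
    paste("chr1", "10", ".", "G", "A,T", ".", "PASS", ".", "GT",
          "0|0", "1|0", sep = "\t"),
    paste("chr1", "20", ".", "C", "CTT", ".", "PASS", ".", "GT",
          "0/0", "1/1", sep = "\t")), tmp)
  v <- read_vcf(tmp)
  # the indel is dropped; the multi-allelic SNV splits, first alt kept first
  expect_equal(v$pos, c(10, 10))
  expect_setequal(v$alt, c("A", "T"))
  expect_equal(v$M1, c("0/1", "0/1"))
  expect_equal(v$WT, c("0/0", "0/0"))
})
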