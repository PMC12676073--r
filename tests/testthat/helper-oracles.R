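# Shared fixtures and independent oracles. Oracles deliberately avoid the
# code paths they check: the consequence oracle works by full-sequence
# mutation and translation instead of codon arithmetic, and the bias
# oracle restates the ideal points literally.

options(homoeocomp.log_level = "WARN")

rc <- function(s) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
        collapse = "")
}

# Brute-force consequence oracle: apply the SNV to the chromosome string,
# re-extract and translate the full CDS before/after, classify from the
# protein diff.
oracle_consequence <- function(variant, model, genome) {
  chrom <- as.character(genome[[model$chrom]])
  stopifnot(substr(chrom, variant$pos, variant$pos) == variant$ref)
  mutated <- chrom
  substr(mutated, variant$pos, variant$pos) <- variant$alt
  extract <- function(s) {
    cds <- paste(substring(s, model$cds$start, model$cds$end), collapse = "")
    if (model$strand == "-") cds <- rc(cds)
    cds
  }
  before <- extract(chrom)
  after <- extract(mutated)
  if (identical(before, after)) return("non_coding")
  tr <- function(s) as.character(Biostrings::translate(
    Biostrings::DNAString(s), no.init.codon = TRUE))
  p_b <- tr(before)
  p_a <- tr(after)
  j <- which(strsplit(before, "")[[1]] != strsplit(after, "")[[1]])
  k <- (j - 1) %/% 3 + 1
  old_codon <- substr(before, (k - 1) * 3 + 1, k * 3)
  aa_old <- substr(p_b, k, k)
  aa_new <- substr(p_a, k, k)
  if (aa_old == "*") return("other")
  if (k == 1 && old_codon == "ATG") return("other")
  if (aa_new == "*") return("PTC")
  if (identical(p_b, p_a)) return("synonymous")
  "missense"
}

# Random single-gene world for consequence fuzzing: random chromosome,
# strand and 1-3 exon CDS (in-frame total length).
random_gene_world <- function(n_codons = 40) {
  bases <- c("A", "C", "G", "T")
  chrom_len <- n_codons * 3 + 400
  chrom <- paste(sample(bases, chrom_len, replace = TRUE), collapse = "")
  n_exon <- sample(1:3, 1)
  len <- n_codons * 3
  cuts <- sort(sample(seq_len(len - 1), n_exon - 1))
  widths <- diff(c(0, cuts, len))
  gap <- sample(20:60, n_exon)
  starts <- 100 + cumsum(c(0, head(widths, -1) + head(gap, n_exon - 1)))
  cds <- data.frame(start = starts, end = starts + widths - 1)
  model <- gene_model("gX", "chrT", sample(c("+", "-"), 1), cds)
  genome <- Biostrings::DNAStringSet(c(chrT = chrom))
  list(model = model, genome = genome)
}

# A tiny deterministic world used by several unit tests: one plus-strand
# single-exon gene and one minus-strand two-exon gene, built by hand.
tiny_world <- function() {
  # gene gp ('+', chr1: 11..31, 21 nt = 7 codons)
  gp_cds <- "ATGTGGCAGCTGAAACCCTAA"  # M W Q L K P *
  # gene gm ('-', chr2): CDS = same sequence, placed reverse-complemented,
  # split into two exons (transcript-first piece rightmost).
  gm_cds <- "ATGTGGCAGCTGAAACCCTAA"
  g_rc <- rc(gm_cds)                  # 21 nt on the forward strand of chr2
  chr1 <- paste0(strrep("A", 10), gp_cds, strrep("C", 10))
  # exon layout on chr2: [5..14] then gap [15..19] then [20..30]
  chr2 <- paste0("GGGG", substr(g_rc, 1, 10), "TTTTT", substr(g_rc, 11, 21),
                 strrep("G", 6))
  genome <- Biostrings::DNAStringSet(c(chr1 = chr1, chr2 = chr2))
  models <- list(
    gp = gene_model("gp", "chr1", "+", data.frame(start = 11, end = 31)),
    gm = gene_model("gm", "chr2", "-",
                    data.frame(start = c(5, 20), end = c(14, 30))))
  list(genome = genome, models = models)
}

# Bias oracle: ideal points restated literally, plain nearest-point scan.
# near_tie marks points whose two best squared distances are within tol:
# there the argmin is not numerically well-defined and implementations may
# legitimately differ, so grid comparisons skip them (the tie-order rule
# is asserted separately on exact ties).
oracle_bias_near_tie <- function(shares, tol = 1e-9) {
  pts <- if (length(shares) == 3) {
    list(c(1, 1, 1) / 3, c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
         c(0, 0.5, 0.5), c(0.5, 0, 0.5), c(0.5, 0.5, 0))
  } else {
    list(c(0.5, 0.5), c(1, 0), c(0, 1))
  }
  d <- sort(vapply(pts, function(p) sqrt(sum((shares - p)^2)), numeric(1)))
  d[2] - d[1] < tol
}

oracle_bias_label <- function(shares) {
  pts <- if (length(shares) == 3) {
    list(Balanced = c(1, 1, 1) / 3,
         A.dominant = c(1, 0, 0), B.dominant = c(0, 1, 0),
         D.dominant = c(0, 0, 1),
         A.suppressed = c(0, 0.5, 0.5), B.suppressed = c(0.5, 0, 0.5),
         D.suppressed = c(0.5, 0.5, 0))
  } else {
    list(Balanced = c(0.5, 0.5), A.dominant = c(1, 0), B.dominant = c(0, 1))
  }
  d <- vapply(pts, function(p) sum((shares - p)^2), numeric(1))
  names(pts)[which.min(d)]
}

# Build a compensation_calls table with given per-class totals and
# compensated counts (one line, unique groups).
synthetic_calls <- function(n_ptc, n_ptc_comp, n_syn = 0, n_syn_comp = 0,
                            line = "L1") {
  n <- n_ptc + n_syn
  data.frame(
    line = line,
    group_id = sprintf("g%04d", seq_len(n)),
    class = rep(c("PTC", "synonymous"), c(n_ptc, n_syn)),
    mutated_subgenome = "A",
    mutated_gene = sprintf("gene%04d", seq_len(n)),
    mutated_status = "down",
    nonmut_statuses = "no_change,no_change",
    n_nonmut_up = c(rep(1L, n_ptc_comp), rep(0L, n_ptc - n_ptc_comp),
                    rep(1L, n_syn_comp), rep(0L, n_syn - n_syn_comp)),
    compensated = c(rep(TRUE, n_ptc_comp), rep(FALSE, n_ptc - n_ptc_comp),
                    rep(TRUE, n_syn_comp), rep(FALSE, n_syn - n_syn_comp)),
    evaluable = TRUE,
    stringsAsFactors = FALSE)
}
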