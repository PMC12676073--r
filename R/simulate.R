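# Synthetic TILLING RNA-seq experiments with known ground truth.
#
# The stated world: one wild-type and one EMS-mutagenised line, 3
# biological replicates each; homoeolog groups are strict triads
# (hexaploid, subgenomes A/B/D) or dyads (tetraploid, A/B); each affected
# group carries exactly one homozygous EMS-signature SNV (G>A on the
# coding strand) in exactly one homoeolog, producing either a premature
# termination codon (TGG>TAG) or a synonymous change (CTG>CTA); PTC
# transcripts are downregulated by an NMD-like multiplicative fold, and a
# configurable fraction of PTC groups additionally upregulate their
# non-mutated homoeologs (true compensation). Counts are negative
# binomial with variance mu + alpha * mu^2.

#' Simulation configuration
#'
#' @param ploidy_mode `"hexaploid"` (triads) or `"tetraploid"` (dyads).
#' @param n_groups number of homoeolog groups.
#' @param n_replicates biological replicates per genotype (default 3,
#'   the sequencing design emulated here).
#' @param baseline_mean_log2_range log2 of the baseline mean expression is
#'   drawn uniformly from this range (default c(6, 9), i.e. means of
#'   64-512: highly expressed seedling-leaf genes).
#' @param nb_dispersion NB dispersion alpha in `Var = mu + alpha mu^2`
#'   (default 0.05, a typical biological-replicate value).
#' @param library_size_factors per-sample multipliers on the mean, length
#'   `2 * n_replicates` (WT replicates first) or a scalar (default 1).
#' @param ptc_fraction fraction of groups given a PTC mutation in one
#'   homoeolog (default 0.4).
#' @param syn_fraction fraction given a synonymous mutation, disjoint from
#'   the PTC groups (default 0.4); `ptc_fraction + syn_fraction <= 1`.
#' @param nmd_fold multiplicative downregulation of the PTC-bearing
#'   homoeolog in the mutant, in (0, 1\] (default 0.15, within the
#'   0.045-0.18 range of observed NMD-affected fold changes).
#' @param compensation_rate fraction of PTC groups whose non-mutated
#'   homoeologs are truly upregulated (default 0.025, the observed
#'   hexaploid headline rate).
#' @param compensation_fold upregulation factor applied to the non-mutated
#'   homoeologs of compensated groups, >= 1 (default 2).
#' @param syn_compensation_rate same for synonymous groups (default 0; a
#'   nonzero value creates a class-equivalent null for calibration
#'   studies).
#' @param wt_shared_snp_rate fraction of emitted variants that are also
#'   homozygous in WT (cultivar-specific SNPs, removed by the
#'   mutant-not-WT filter; default 0).
#' @param heterozygous_rate fraction of emitted variants left heterozygous
#'   in the mutant line (removed by the homozygosity filter; default 0).
#' @param seed integer RNG seed.
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(ploidy_mode = c("hexaploid", "tetraploid"),
                              n_groups = 100,
                              n_replicates = 3,
                              baseline_mean_log2_range = c(6, 9),
                              nb_dispersion = 0.05,
                              library_size_factors = 1,
                              ptc_fraction = 0.4,
                              syn_fraction = 0.4,
                              nmd_fold = 0.15,
                              compensation_rate = 0.025,
                              compensation_fold = 2,
                              syn_compensation_rate = 0,
                              wt_shared_snp_rate = 0,
                              heterozygous_rate = 0,
                              seed = 1L) {
  ploidy_mode <- match.arg(ploidy_mode)
  chk_frac <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
      stop_field(nm, "must be a single number in [0, 1]")
    }
  }
  if (!is.numeric(n_groups) || n_groups < 1 || n_groups != round(n_groups)) {
    stop_field("n_groups", "must be a positive integer")
  }
  if (!is.numeric(n_replicates) || n_replicates < 1 ||
      n_replicates != round(n_replicates)) {
    stop_field("n_replicates", "must be a positive integer")
  }
  if (length(baseline_mean_log2_range) != 2 ||
      diff(baseline_mean_log2_range) < 0) {
    stop_field("baseline_mean_log2_range", "must be an increasing pair")
  }
  if (!is.numeric(nb_dispersion) || nb_dispersion < 0) {
    stop_field("nb_dispersion", "must be a non-negative number")
  }
  n_samples <- 2L * as.integer(n_replicates)
  if (length(library_size_factors) == 1) {
    library_size_factors <- rep(library_size_factors, n_samples)
  }
  if (length(library_size_factors) != n_samples ||
      any(library_size_factors <= 0)) {
    stop_field("library_size_factors",
               sprintf("must be %d positive values", n_samples))
  }
  chk_frac(ptc_fraction, "ptc_fraction")
  chk_frac(syn_fraction, "syn_fraction")
  if (ptc_fraction + syn_fraction > 1 + 1e-12) {
    stop_field("syn_fraction", "ptc_fraction + syn_fraction must be <= 1")
  }
  if (!is.numeric(nmd_fold) || nmd_fold <= 0 || nmd_fold > 1) {
    stop_field("nmd_fold", "must lie in (0, 1]")
  }
  chk_frac(compensation_rate, "compensation_rate")
  chk_frac(syn_compensation_rate, "syn_compensation_rate")
  if (!is.numeric(compensation_fold) || compensation_fold < 1) {
    stop_field("compensation_fold", "must be >= 1")
  }
  chk_frac(wt_shared_snp_rate, "wt_shared_snp_rate")
  chk_frac(heterozygous_rate, "heterozygous_rate")
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop_field("seed", "must be a single integer")
  }
  structure(list(ploidy_mode = ploidy_mode,
                 n_groups = as.integer(n_groups),
                 n_replicates = as.integer(n_replicates),
                 baseline_mean_log2_range = baseline_mean_log2_range,
                 nb_dispersion = nb_dispersion,
                 library_size_factors = library_size_factors,
                 ptc_fraction = ptc_fraction, syn_fraction = syn_fraction,
                 nmd_fold = nmd_fold,
                 compensation_rate = compensation_rate,
                 compensation_fold = compensation_fold,
                 syn_compensation_rate = syn_compensation_rate,
                 wt_shared_snp_rate = wt_shared_snp_rate,
                 heterozygous_rate = heterozygous_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Fixed gene architecture: 100 codons (ATG + 98 internal + TAA), genes
# spaced on one chromosome per subgenome; strand and single/two-exon
# structure cycle with the group index so all four combinations occur.
SIM_N_CODONS <- 100L
SIM_SLOT <- 700L

# codons that never encode stop, start-irrelevant, used as CDS filler;
# TGG/CTG excluded so only planted mutation sites carry those codons.
sim_filler_codons <- function() {
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA", "TGG", "CTG"))
}

#' Simulate a TILLING RNA-seq experiment
#'
#' @param config a [simulation_config()].
#' @return A list of class `hc_simulation`: `counts` (a
#'   [count_matrix()]), `variants` (table as from [read_vcf()]), `groups`
#'   (a [homoeolog_groups()] table), `models` (gene model list), `genome`
#'   (`DNAStringSet`), `truth` (per-group data.frame with `mutation_class`,
#'   `mutated_subgenome`, `mutated_gene`, `compensated` and true
#'   mutant/WT fold changes `fc_A`, `fc_B`, `fc_D`), and `config`.
#'   Identical configurations (including `seed`) give identical output.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sg <- if (config$ploidy_mode == "hexaploid") c("A", "B", "D") else c("A", "B")
  n_g <- config$n_groups
  n_rep <- config$n_replicates
  filler <- sim_filler_codons()

  gid <- sprintf("grp%04d", seq_len(n_g))
  gene_ids <- outer(sprintf("TraesSYN%04dG", seq_len(n_g)), sg, paste0)
  colnames(gene_ids) <- sg
  groups <- homoeolog_groups(gid, gene_ids[, "A"], gene_ids[, "B"],
                             if ("D" %in% sg) gene_ids[, "D"] else NA)

  # mutation classes and compensation truth
  n_ptc <- round(config$ptc_fraction * n_g)
  n_syn <- round(config$syn_fraction * n_g)
  cls <- rep("none", n_g)
  pick <- sample.int(n_g, n_ptc + n_syn)
  cls[pick[seq_len(n_ptc)]] <- "PTC"
  if (n_syn > 0) cls[pick[n_ptc + seq_len(n_syn)]] <- "synonymous"
  mut_sg <- ifelse(cls == "none", NA_character_,
                   sg[sample.int(length(sg), n_g, replace = TRUE)])
  comp <- rep(FALSE, n_g)
  comp[cls == "PTC"] <- rbinom(sum(cls == "PTC"), 1,
                               config$compensation_rate) == 1
  comp[cls == "synonymous"] <- rbinom(sum(cls == "synonymous"), 1,
                                      config$syn_compensation_rate) == 1

  # genome, gene models, variants
  chrom_names <- paste0("chr1", sg)
  chrom_len <- n_g * SIM_SLOT + 200L
  chrom_seq <- setNames(lapply(chrom_names, function(ch) {
    sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
  }), chrom_names)

  models <- vector("list", n_g * length(sg))
  names(models) <- as.vector(t(gene_ids))
  var_rows <- list()
  mut_codon <- sample(2:(SIM_N_CODONS - 2L), n_g, replace = TRUE)

  for (i in seq_len(n_g)) {
    codons <- c("ATG", sample(filler, SIM_N_CODONS - 2L, replace = TRUE),
                "TAA")
    for (s in sg) {
      g <- gene_ids[i, s]
      ch <- paste0("chr1", s)
      my_codons <- codons
      is_mut <- !is.na(mut_sg[i]) && mut_sg[i] == s
      if (is_mut) {
        my_codons[mut_codon[i]] <-
          if (cls[i] == "PTC") "TGG" else "CTG"
      }
      cds <- paste(my_codons, collapse = "")
      start <- (i - 1L) * SIM_SLOT + 101L
      len <- 3L * SIM_N_CODONS
      two_exon <- i %% 2L == 0L
      strand <- if ((i %% 4L) %in% c(2L, 3L)) "-" else "+"
      ivl <- if (two_exon) {
        data.frame(start = c(start, start + 151L + 60L),
                   end = c(start + 150L, start + 151L + 60L + (len - 151L) - 1L))
      } else {
        data.frame(start = start, end = start + len - 1L)
      }
      m <- gene_model(g, ch, strand, ivl)
      models[[g]] <- m
      genomic <- if (strand == "+") cds else revcomp_chr(cds)
      offs <- 0L
      for (r in seq_len(nrow(ivl))) {
        w <- ivl$end[r] - ivl$start[r] + 1L
        chrom_seq[[ch]][ivl$start[r]:ivl$end[r]] <-
          strsplit(substr(genomic, offs + 1L, offs + w), "")[[1]]
        offs <- offs + w
      }
      if (is_mut) {
        within <- if (cls[i] == "PTC") 2L else 3L   # TGG>TAG / CTG>CTA
        cp <- (mut_codon[i] - 1L) * 3L + within
        gpos <- cds_to_genomic(m, cp)
        ref <- if (strand == "+") "G" else "C"      # EMS: G>A / C>T
        alt <- if (strand == "+") "A" else "T"
        wt_gt <- if (runif(1) < config$wt_shared_snp_rate) "1/1" else "0/0"
        mut_gt <- if (runif(1) < config$heterozygous_rate) "0/1" else "1/1"
        var_rows[[length(var_rows) + 1]] <- data.frame(
          chrom = ch, pos = gpos, ref = ref, alt = alt,
          csq = if (cls[i] == "PTC") "stop_gained" else "synonymous_variant",
          WT = wt_gt, M1 = mut_gt, stringsAsFactors = FALSE)
      }
    }
  }
  genome <- Biostrings::DNAStringSet(
    vapply(chrom_seq, paste, "", collapse = ""))
  variants <- if (length(var_rows)) do.call(rbind, var_rows) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), csq = character(), WT = character(),
               M1 = character(), stringsAsFactors = FALSE)
  variants <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
  rownames(variants) <- NULL
  attr(variants, "samples") <- c("WT", "M1")

  # true fold changes per homoeolog (mutant vs WT)
  fc <- matrix(1, n_g, length(sg), dimnames = list(gid, sg))
  for (i in seq_len(n_g)) {
    if (cls[i] == "PTC") fc[i, mut_sg[i]] <- config$nmd_fold
    if (comp[i]) {
      others <- setdiff(sg, mut_sg[i])
      fc[i, others] <- config$compensation_fold
    }
  }

  # counts
  all_genes <- as.vector(t(gene_ids))                 # group-major, A,B,D
  baseline <- 2^runif(length(all_genes),
                      config$baseline_mean_log2_range[1],
                      config$baseline_mean_log2_range[2])
  fc_gene <- as.vector(t(fc))
  samples <- data.frame(
    sample = c(paste0("WT_", seq_len(n_rep)), paste0("M1_", seq_len(n_rep))),
    genotype = rep(c("WT", "M1"), each = n_rep),
    replicate = rep(seq_len(n_rep), 2),
    stringsAsFactors = FALSE)
  mu <- outer(baseline, rep(1, 2 * n_rep))
  mu[, samples$genotype == "M1"] <-
    mu[, samples$genotype == "M1"] * fc_gene
  mu <- sweep(mu, 2, config$library_size_factors, "*")
  cnt <- if (config$nb_dispersion > 0) {
    matrix(rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
           nrow = nrow(mu))
  } else {
    matrix(rpois(length(mu), mu), nrow = nrow(mu))
  }
  storage.mode(cnt) <- "integer"
  dimnames(cnt) <- list(all_genes, samples$sample)

  truth <- data.frame(group_id = gid, mutation_class = cls,
                      mutated_subgenome = mut_sg,
                      mutated_gene = gene_ids[cbind(seq_len(n_g),
                                                    match(mut_sg, sg))],
                      compensated = comp,
                      fc_A = fc[, "A"], fc_B = fc[, "B"],
                      fc_D = if ("D" %in% sg) fc[, "D"] else NA_real_,
                      stringsAsFactors = FALSE)
  rownames(truth) <- NULL

  structure(list(counts = count_matrix(cnt, samples), variants = variants,
                 groups = groups, models = models, genome = genome,
                 truth = truth, config = config),
            class = "hc_simulation")
}

# plain-character reverse complement; avoids per-gene S4 dispatch cost
revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

#' Write simulation outputs as plain-text fixtures
#'
#' Emits `counts.tsv`, `samples.tsv`, `variants.vcf`, `groups.tsv`,
#' `genes.gff3`, `genome.fa` and `truth.tsv` into `directory`; all files
#' round-trip through the package's readers.
#'
#' @param sim an `hc_simulation` from [simulate_experiment()].
#' @param directory output directory (created if absent).
#' @return Named character vector of the file paths, invisibly.
#' @export
write_fixtures <- function(sim, directory) {
  stopifnot(inherits(sim, "hc_simulation"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory ", directory, call. = FALSE)
  }
  p <- function(f) file.path(directory, f)
  write_counts(sim$counts, p("counts.tsv"), p("samples.tsv"))
  write_vcf(sim$variants, p("variants.vcf"),
            contigs = setNames(Biostrings::width(sim$genome),
                               names(sim$genome)))
  write_groups(sim$groups, p("groups.tsv"))
  write_gff3(sim$models, p("genes.gff3"))
  Biostrings::writeXStringSet(sim$genome, p("genome.fa"))
  write_tsv(sim$truth, p("truth.tsv"))
  invisible(c(counts = p("counts.tsv"), samples = p("samples.tsv"),
              variants = p("variants.vcf"), groups = p("groups.tsv"),
              gff = p("genes.gff3"), genome = p("genome.fa"),
              truth = p("truth.tsv")))
}

#' Write gene models as GFF3 (gene/mRNA/CDS)
#' @param models gene model list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  feats <- lapply(models, function(m) {
    span <- c(min(m$cds$start), max(m$cds$end))
    g <- GenomicRanges::GRanges(
      m$chrom,
      IRanges::IRanges(c(span[1], span[1], m$cds$start),
                       c(span[2], span[2], m$cds$end)),
      strand = m$strand)
    g$type <- c("gene", "mRNA", rep("CDS", nrow(m$cds)))
    g$ID <- c(m$gene_id, paste0(m$gene_id, ".1"),
              rep(NA_character_, nrow(m$cds)))
    g$Parent <- c(NA_character_, m$gene_id,
                  rep(paste0(m$gene_id, ".1"), nrow(m$cds)))
    g$phase <- NA_integer_
    # GFF3 requires CDS phase; transcript-ordered cumulative length mod 3
    w <- m$cds$end - m$cds$start + 1L
    ord <- if (m$strand == "+") seq_len(nrow(m$cds)) else rev(seq_len(nrow(m$cds)))
    ph <- (3L - (cumsum(c(0L, w[ord]))[seq_len(nrow(m$cds))] %% 3L)) %% 3L
    g$phase[2 + ord] <- ph
    g
  })
  gr <- suppressWarnings(do.call(c, unname(feats)))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a fixture directory written by write_fixtures()
#' @param directory fixture directory.
#' @param csq_key INFO key for VCF consequence annotation.
#' @return A list with `counts`, `variants`, `groups`, `models`, `genome`
#'   and, when present, `truth`.
#' @export
read_fixtures <- function(directory, csq_key = "CSQ") {
  p <- function(f) file.path(directory, f)
  for (f in c("counts.tsv", "samples.tsv", "variants.vcf", "groups.tsv",
              "genes.gff3", "genome.fa")) {
    if (!file.exists(p(f))) stop("missing fixture file ", p(f), call. = FALSE)
  }
  out <- list(counts = read_counts(p("counts.tsv"), p("samples.tsv")),
              variants = read_vcf(p("variants.vcf"), csq_key = csq_key),
              groups = read_groups(p("groups.tsv")),
              models = read_gene_models(p("genes.gff3")),
              genome = read_genome(p("genome.fa")))
  if (file.exists(p("truth.tsv"))) out$truth <- read_tsv(p("truth.tsv"))
  out
}
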