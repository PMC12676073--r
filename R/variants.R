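# SNV consequence calling against gene models, and the TILLING variant
# filtering cascade: keep PTC/synonymous changes that are homozygous in a
# mutant line, absent from wild type, and fall in a homoeolog-group gene.

CONSEQUENCES <- c("PTC", "synonymous", "missense", "non_coding", "other")

# VEP-style terms accepted when consequences are taken from the VCF INFO
# field rather than called internally.
VEP_TERM_MAP <- c(stop_gained = "PTC",
                  synonymous_variant = "synonymous",
                  missense_variant = "missense",
                  stop_lost = "other",
                  start_lost = "other",
                  intergenic_variant = "non_coding",
                  intron_variant = "non_coding",
                  upstream_gene_variant = "non_coding",
                  downstream_gene_variant = "non_coding")

# --- VCF I/O ----------------------------------------------------------------

#' Read SNVs and per-line genotypes from a VCF
#'
#' Multi-allelic sites are split and only the first alternate allele of
#' each split record is considered; records whose ref or (first) alt is not
#' a single nucleotide are dropped. Genotypes are normalised to
#' `0/0`, `0/1`, `1/1` or `./.` (phased separators collapsed, alleles
#' sorted).
#'
#' @param path VCF v4.2 file.
#' @param csq_key INFO key carrying an optional pre-annotated consequence
#'   (default `"CSQ"`).
#' @param csq_field 1-based index of the consequence term within the
#'   `|`-separated annotation string (default 1).
#' @return A `data.frame` with columns `chrom`, `pos`, `ref`, `alt`, `csq`
#'   (`NA` when unannotated) and one genotype column per VCF sample;
#'   attribute `"samples"` lists the genotype columns.
#' @export
read_vcf <- function(path, csq_key = "CSQ", csq_field = 1L) {
  vcf <- VariantAnnotation::readVcf(path)
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  alt <- as.character(rr$ALT)
  keep <- nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (any(!keep)) {
    hc_log("DEBUG", "read_vcf: dropped %d non-SNV record(s)", sum(!keep))
  }
  vcf <- vcf[keep]
  rr <- rr[keep]
  csq <- rep(NA_character_, length(rr))
  info <- VariantAnnotation::info(vcf)
  if (csq_key %in% names(info)) {
    raw <- info[[csq_key]]
    raw <- vapply(as.list(raw), function(x) {
      if (length(x) == 0 || is.na(x[1])) NA_character_ else as.character(x[1])
    }, character(1))
    csq <- vapply(strsplit(raw, "|", fixed = TRUE), function(p) {
      if (length(p) >= csq_field) p[csq_field] else NA_character_
    }, character(1))
  }
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT FORMAT field: ", path, call. = FALSE)
  norm_gt <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    parts <- strsplit(g, "/", fixed = TRUE)
    vapply(parts, function(p) {
      if (length(p) != 2 || any(p == ".")) "./."
      else paste(sort(p), collapse = "/")
    }, character(1))
  }
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
                    pos = GenomicRanges::start(rr),
                    ref = ref[keep], alt = alt[keep], csq = csq,
                    stringsAsFactors = FALSE)
  for (s in colnames(gt)) out[[s]] <- norm_gt(gt[, s])
  rownames(out) <- NULL
  attr(out, "samples") <- colnames(gt)
  out
}

#' Write a variant table as VCF v4.2
#'
#' @param variants a variant `data.frame` as returned by [read_vcf()] (the
#'   `csq` column, when non-`NA`, is emitted under `csq_key`).
#' @param path output path.
#' @param csq_key INFO key for the consequence annotation.
#' @param contigs optional named integer vector of contig lengths for
#'   `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, csq_key = "CSQ", contigs = NULL) {
  samples <- attr(variants, "samples")
  if (is.null(samples)) {
    samples <- setdiff(names(variants), c("chrom", "pos", "ref", "alt", "csq"))
  }
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##INFO=<ID=%s,Number=.,Type=String,Description=\"Consequence annotation\">",
                   csq_key),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  if (!is.null(contigs)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                          as.integer(contigs)))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", samples),
                      collapse = "\t"))
  body <- if (nrow(variants) == 0) character(0) else {
    info <- ifelse(is.na(variants$csq), ".",
                   paste0(csq_key, "=", variants$csq))
    do.call(paste, c(list(variants$chrom, variants$pos, ".",
                          variants$ref, variants$alt, ".", "PASS",
                          info, "GT"),
                     lapply(samples, function(s) variants[[s]]),
                     sep = "\t"))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

# --- Consequence calling ----------------------------------------------------

#' Call the coding consequence of a single-nucleotide variant
#'
#' The affected codon is translated before and after the substitution with
#' the standard genetic code. A new stop codon where the reference had none
#' is a premature termination codon (`"PTC"`); an unchanged amino acid is
#' `"synonymous"`; a changed amino acid is `"missense"`. Changes that lose
#' the reference stop or the start codon — including a stop codon mutating
#' to a different stop — are `"other"`. Positions outside the CDS return
#' `"non_coding"`.
#'
#' @param variant a list or one-row data.frame with `chrom`, `pos` (1-based
#'   genomic), `ref`, `alt` (single nucleotides, forward strand).
#' @param model a [gene_model()].
#' @param genome a `DNAStringSet`.
#' @return One of `"PTC"`, `"synonymous"`, `"missense"`, `"non_coding"`,
#'   `"other"`.
#' @export
call_consequence <- function(variant, model, genome) {
  if (variant$chrom != model$chrom) return("non_coding")
  cds_pos <- genomic_to_cds(model, variant$pos)
  if (is.na(cds_pos)) return("non_coding")
  if (!model$frame_ok) {
    stop("CDS length of gene model ", model$gene_id,
         " is not divisible by 3", call. = FALSE)
  }
  cds <- as.character(cds_sequence(model, genome))
  ref <- variant$ref
  alt <- variant$alt
  if (model$strand == "-") {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    ref <- comp[[ref]]
    alt <- comp[[alt]]
  }
  if (substr(cds, cds_pos, cds_pos) != ref) {
    stop(sprintf("ref allele mismatch at %s:%d for gene %s (expected %s)",
                 variant$chrom, variant$pos, model$gene_id,
                 substr(cds, cds_pos, cds_pos)), call. = FALSE)
  }
  codon_i <- (cds_pos - 1L) %/% 3L
  codon <- substr(cds, codon_i * 3L + 1L, codon_i * 3L + 3L)
  within <- cds_pos - codon_i * 3L
  new_codon <- codon
  substr(new_codon, within, within) <- alt
  aa_old <- Biostrings::GENETIC_CODE[[codon]]
  aa_new <- Biostrings::GENETIC_CODE[[new_codon]]
  is_start <- codon_i == 0L
  if (aa_old == "*") return("other")                 # stop lost or retained
  if (is_start && codon == "ATG" && new_codon != "ATG") return("other")
  if (aa_new == "*") return("PTC")
  if (aa_new == aa_old) return("synonymous")
  "missense"
}

# --- Filtering cascade ------------------------------------------------------

#' Apply the TILLING variant filtering cascade
#'
#' A variant is assigned to a mutant line when (i) its consequence is PTC
#' or synonymous, (ii) the line is homozygous for the alternate allele,
#' (iii) the affected gene belongs to a homoeolog group, and (iv) wild type
#' is homozygous reference (removing cultivar-specific SNPs). Variants
#' falling in no gene model are dropped with a debug log entry. When a gene
#' carries several qualifying variants in the same line, one assignment is
#' kept (PTC over synonymous, then the 5'-most change).
#'
#' @param variants variant `data.frame` from [read_vcf()], genotype columns
#'   named per line.
#' @param groups a [homoeolog_groups()] table.
#' @param models gene model list from [read_gene_models()].
#' @param genome `DNAStringSet`; required unless `annotation = "info"`.
#' @param wt_line genotype column holding the wild-type line (default
#'   `"WT"`).
#' @param lines mutant line columns to use; default all non-WT genotype
#'   columns.
#' @param annotation `"internal"` calls consequences from the gene models,
#'   `"info"` trusts the VCF annotation, `"auto"` (default) uses the
#'   annotation when present and calls internally otherwise.
#' @param on_missing_wt `"error"` (default) or `"drop"` for records without
#'   a WT genotype.
#' @return A `data.frame` of mutation assignments: `line`, `gene_id`,
#'   `group_id`, `subgenome`, `consequence` (`"PTC"`/`"synonymous"`),
#'   `cds_pos`, `chrom`, `pos`. Attribute `"filter_counts"` records the
#'   record count surviving each filter.
#' @export
filter_mutations <- function(variants, groups, models, genome = NULL,
                             wt_line = "WT", lines = NULL,
                             annotation = c("auto", "info", "internal"),
                             on_missing_wt = c("error", "drop")) {
  annotation <- match.arg(annotation)
  on_missing_wt <- match.arg(on_missing_wt)
  samples <- attr(variants, "samples")
  if (is.null(samples)) {
    samples <- setdiff(names(variants), c("chrom", "pos", "ref", "alt", "csq"))
  }
  if (!wt_line %in% samples) {
    stop("wild-type line ", wt_line, " not genotyped in variant table",
         call. = FALSE)
  }
  if (is.null(lines)) lines <- setdiff(samples, wt_line)
  lookup <- group_lookup(groups)
  counts <- c(input = nrow(variants))

  # locate the gene model containing each variant
  by_chrom <- split(seq_along(models), vapply(models, `[[`, "", "chrom"))
  gene_of <- rep(NA_integer_, nrow(variants))
  for (ch in names(by_chrom)) {
    idx <- by_chrom[[ch]]
    ir <- IRanges::IRanges(
      start = unlist(lapply(models[idx], function(m) m$cds$start)),
      end = unlist(lapply(models[idx], function(m) m$cds$end)))
    owner <- rep(idx, vapply(models[idx], function(m) nrow(m$cds), 0L))
    v <- which(variants$chrom == ch)
    if (length(v) == 0) next
    hits <- IRanges::findOverlaps(IRanges::IRanges(variants$pos[v], width = 1L), ir)
    gene_of[v[S4Vectors::queryHits(hits)]] <- owner[S4Vectors::subjectHits(hits)]
  }
  in_gene <- !is.na(gene_of)
  if (any(!in_gene)) {
    hc_log("DEBUG", "filter_mutations: %d variant(s) outside any CDS dropped",
           sum(!in_gene))
  }
  counts["in_cds"] <- sum(in_gene)

  csq <- rep(NA_character_, nrow(variants))
  for (i in which(in_gene)) {
    m <- models[[gene_of[i]]]
    ann <- variants$csq[i]
    if (annotation == "info" || (annotation == "auto" && !is.na(ann))) {
      if (is.na(ann)) {
        stop("annotation = \"info\" but record ", i, " has no consequence",
             call. = FALSE)
      }
      csq[i] <- if (ann %in% names(VEP_TERM_MAP)) VEP_TERM_MAP[[ann]] else "other"
    } else {
      if (is.null(genome)) {
        stop("internal consequence calling requires `genome`", call. = FALSE)
      }
      csq[i] <- call_consequence(variants[i, ], m, genome)
    }
  }
  class_ok <- in_gene & csq %in% c("PTC", "synonymous")
  counts["ptc_or_syn"] <- sum(class_ok)

  gene_ids <- vapply(models, `[[`, "", "gene_id")
  member <- class_ok & gene_ids[gene_of] %in% lookup$gene_id
  counts["in_group"] <- sum(member)

  wt_gt <- variants[[wt_line]]
  missing_wt <- member & wt_gt == "./."
  if (any(missing_wt)) {
    if (on_missing_wt == "error") {
      stop(sum(missing_wt), " variant(s) lack a wild-type genotype",
           call. = FALSE)
    }
    member <- member & !missing_wt
  }
  wt_ref <- member & wt_gt == "0/0"
  counts["wt_ref"] <- sum(wt_ref)

  rows <- list()
  for (ln in lines) {
    gt <- variants[[ln]]
    keep <- which(wt_ref & gt == "1/1")
    if (length(keep) == 0) next
    gid <- gene_ids[gene_of[keep]]
    li <- match(gid, lookup$gene_id)
    rows[[ln]] <- data.frame(
      line = ln, gene_id = gid,
      group_id = lookup$group_id[li], subgenome = lookup$subgenome[li],
      consequence = csq[keep],
      cds_pos = vapply(keep, function(i)
        genomic_to_cds(models[[gene_of[i]]], variants$pos[i]), 0L),
      chrom = variants$chrom[keep], pos = variants$pos[keep],
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(line = character(), gene_id = character(),
               group_id = character(), subgenome = character(),
               consequence = character(), cds_pos = integer(),
               chrom = character(), pos = integer(),
               stringsAsFactors = FALSE)
  counts["hom_in_mutant"] <- nrow(out)

  # one assignment per (line, gene): PTC beats synonymous, then 5'-most
  if (nrow(out) > 1) {
    ord <- order(out$line, out$gene_id,
                 match(out$consequence, c("PTC", "synonymous")), out$cds_pos)
    out <- out[ord, , drop = FALSE]
    out <- out[!duplicated(out[, c("line", "gene_id")]), , drop = FALSE]
  }
  rownames(out) <- NULL
  counts["assignments"] <- nrow(out)
  for (nm in names(counts)) {
    hc_log("INFO", "filter_mutations: %-14s %d", nm, counts[[nm]])
  }
  attr(out, "filter_counts") <- counts
  out
}

#' Reduce mutation assignments to analyzable (line, group) contexts
#'
#' A context is analyzable when exactly one homoeolog of the group carries
#' a qualifying mutation in that line. Groups with more than one mutated
#' homoeolog in the same line are excluded and counted — including groups
#' carrying a PTC in one homoeolog and a synonymous change in another,
#' which therefore never enter the synonymous class.
#'
#' @param assignments output of [filter_mutations()].
#' @return A `data.frame` of contexts: `line`, `group_id`, `class`,
#'   `subgenome` (mutated), `gene_id` (mutated), `cds_pos`. Attribute
#'   `"excluded"` is a data.frame of (line, group) pairs removed for
#'   multiple mutated homoeologs.
#' @export
assign_groups <- function(assignments) {
  key <- paste(assignments$line, assignments$group_id, sep = "\r")
  n_mut <- table(key)
  multi <- names(n_mut)[n_mut > 1]
  single <- !key %in% multi
  out <- assignments[single, c("line", "group_id", "consequence",
                               "subgenome", "gene_id", "cds_pos")]
  names(out)[names(out) == "consequence"] <- "class"
  rownames(out) <- NULL
  excl <- unique(assignments[!single, c("line", "group_id")])
  rownames(excl) <- NULL
  if (nrow(excl) > 0) {
    hc_log("INFO",
           "assign_groups: excluded %d (line, group) context(s) with >1 mutated homoeolog",
           nrow(excl))
  }
  attr(out, "excluded") <- excl
  out
}
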