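# Homoeolog group tables, gene models (GFF3) and genome sequence access.
#
# Coordinate conventions: GFF3 and VCF are 1-based inclusive and are kept
# that way in the stored intervals; CDS-relative positions handed to the
# consequence caller are 1-based along the spliced coding sequence in
# transcript orientation. All conversions happen in cds_to_genomic() /
# genomic_to_cds() only.

SUBGENOMES <- c("A", "B", "D")

# --- Homoeolog groups -------------------------------------------------------

#' Build a homoeolog group table
#'
#' A group is a strict 1:1(:1) set of homoeologs: one gene per subgenome,
#' three for hexaploid triads (A, B, D) or two for tetraploid dyads (A, B).
#'
#' @param group_id character vector of unique group identifiers.
#' @param gene_A,gene_B character vectors of member gene ids.
#' @param gene_D character vector of D-subgenome members, or `NA`/`""`
#'   throughout for dyads.
#' @return A `data.frame` of class `homoeolog_groups` with columns
#'   `group_id`, `gene_A`, `gene_B`, `gene_D` (`NA` for dyads) and
#'   `cardinality` (`"triad"` or `"dyad"`).
#' @export
homoeolog_groups <- function(group_id, gene_A, gene_B, gene_D = NA) {
  df <- data.frame(group_id = as.character(group_id),
                   gene_A = as.character(gene_A),
                   gene_B = as.character(gene_B),
                   gene_D = as.character(gene_D),
                   stringsAsFactors = FALSE)
  df$gene_D[!is.na(df$gene_D) & df$gene_D == ""] <- NA_character_
  df$cardinality <- ifelse(is.na(df$gene_D), "dyad", "triad")
  validate_groups(df)
  class(df) <- c("homoeolog_groups", "data.frame")
  df
}

validate_groups <- function(df) {
  if (anyDuplicated(df$group_id)) {
    stop("duplicate group_id: ",
         paste(unique(df$group_id[duplicated(df$group_id)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- is.na(df$gene_A) | df$gene_A == "" | is.na(df$gene_B) | df$gene_B == ""
  if (any(bad)) {
    stop("group(s) with fewer than 2 members: ",
         paste(df$group_id[bad], collapse = ", "), call. = FALSE)
  }
  genes <- unlist(group_members(df), use.names = FALSE)
  if (anyDuplicated(genes)) {
    stop("gene id present in more than one group (or twice in one): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}

group_members <- function(groups) {
  lapply(seq_len(nrow(groups)), function(i) {
    m <- c(A = groups$gene_A[i], B = groups$gene_B[i], D = groups$gene_D[i])
    m[!is.na(m)]
  })
}

#' Read a homoeolog group TSV
#'
#' Expected columns: `group_id`, `gene_A`, `gene_B`, `gene_D` (the last
#' empty for tetraploid dyads). Genes appearing in more than one group and
#' groups with fewer than two members are rejected.
#'
#' @param path path to the TSV file.
#' @return A [homoeolog_groups()] table.
#' @export
read_groups <- function(path) {
  df <- read_tsv(path, colClasses = "character")
  need <- c("group_id", "gene_A", "gene_B")
  if (!all(need %in% names(df))) {
    stop("malformed group table, missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  if (!"gene_D" %in% names(df)) df$gene_D <- NA_character_
  homoeolog_groups(df$group_id, df$gene_A, df$gene_B, df$gene_D)
}

#' Write a homoeolog group TSV
#' @param groups a [homoeolog_groups()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_groups <- function(groups, path) {
  out <- groups[, c("group_id", "gene_A", "gene_B", "gene_D")]
  out$gene_D[is.na(out$gene_D)] <- ""
  write_tsv(out, path)
}

#' Gene-to-group lookup
#'
#' @param groups a [homoeolog_groups()] table.
#' @return A `data.frame` with one row per member gene: `gene_id`,
#'   `group_id`, `subgenome`. Total over all member genes and unique per
#'   gene (enforced at construction).
#' @export
group_lookup <- function(groups) {
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    m <- group_members(groups[i, , drop = FALSE])[[1]]
    data.frame(gene_id = unname(m), group_id = groups$group_id[i],
               subgenome = names(m), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# --- Gene models ------------------------------------------------------------

#' Read gene models from GFF3
#'
#' Keeps CDS features and groups them per gene (via the `Parent`/`ID`
#' chain, falling back to the CDS `Parent` when mRNA records are absent).
#' Models whose total CDS length is not a multiple of 3 are flagged in the
#' `frame_ok` field and rejected later by the consequence caller.
#'
#' @param path GFF3 file with gene/mRNA/CDS features.
#' @return A named list of gene models; each model is a list with
#'   `gene_id`, `chrom`, `strand` and `cds`, a data.frame of 1-based
#'   inclusive `start`/`end` intervals sorted by genomic start.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  cds <- gr[gr$type == "CDS"]
  if (length(cds) == 0) stop("no CDS features in ", path, call. = FALSE)
  first_chr <- function(x) vapply(as.list(x), function(v)
    if (length(v)) as.character(v[1]) else NA_character_, character(1))
  parent <- first_chr(cds$Parent)
  # map mRNA -> gene where mRNA records exist
  mrna <- gr[gr$type == "mRNA"]
  if (length(mrna) > 0) {
    m2g <- setNames(first_chr(mrna$Parent), as.character(mrna$ID))
    hit <- parent %in% names(m2g)
    parent[hit] <- m2g[parent[hit]]
  }
  parent <- sub("^(gene:|transcript:)", "", parent)
  idx <- split(seq_along(cds), parent)
  models <- lapply(names(idx), function(g) {
    i <- idx[[g]]
    ivl <- data.frame(start = GenomicRanges::start(cds)[i],
                      end = GenomicRanges::end(cds)[i])
    ivl <- ivl[order(ivl$start), , drop = FALSE]
    rownames(ivl) <- NULL
    if (any(ivl$end[-nrow(ivl)] >= ivl$start[-1])) {
      stop("overlapping CDS intervals in gene model ", g, call. = FALSE)
    }
    gene_model(g,
               chrom = as.character(GenomicRanges::seqnames(cds))[i[1]],
               strand = as.character(GenomicRanges::strand(cds))[i[1]],
               cds = ivl)
  })
  setNames(models, names(idx))
}

#' Construct a gene model
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param cds data.frame with 1-based inclusive `start`, `end` columns.
#' @return A `gene_model` list; `cds_len` is the spliced CDS length and
#'   `frame_ok` records whether it is divisible by 3.
#' @export
gene_model <- function(gene_id, chrom, strand, cds) {
  stopifnot(strand %in% c("+", "-"), nrow(cds) >= 1,
            all(cds$end >= cds$start))
  cds <- cds[order(cds$start), c("start", "end"), drop = FALSE]
  cds$start <- as.integer(cds$start)
  cds$end <- as.integer(cds$end)
  len <- sum(cds$end - cds$start + 1L)
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 cds = cds, cds_len = len, frame_ok = len %% 3L == 0L),
            class = "gene_model")
}

#' Read a genome FASTA into a DNAStringSet
#' @param path FASTA path (multi-record, line-wrapped accepted).
#' @return A [Biostrings::DNAStringSet] named by sequence id.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Spliced coding sequence of a gene model
#'
#' Exon substrings are concatenated in transcript orientation; minus-strand
#' models are reverse-complemented, so the result always starts at the
#' first codon.
#'
#' @param model a [gene_model()].
#' @param genome a `DNAStringSet` containing `model$chrom`.
#' @return A `DNAString` with the coding sequence.
#' @export
cds_sequence <- function(model, genome) {
  chrom <- genome[[model$chrom]]
  if (any(model$cds$start < 1L) || any(model$cds$end > length(chrom))) {
    stop("CDS interval out of chromosome bounds for gene ", model$gene_id,
         call. = FALSE)
  }
  pieces <- Biostrings::DNAStringSet(chrom, start = model$cds$start,
                                     end = model$cds$end)
  s <- Biostrings::DNAString(paste(as.character(pieces), collapse = ""))
  if (model$strand == "-") s <- Biostrings::reverseComplement(s)
  s
}

# --- Coordinate conversion --------------------------------------------------

#' Genomic position of a 1-based CDS coordinate
#' @noRd
cds_to_genomic <- function(model, cds_pos) {
  stopifnot(cds_pos >= 1L, cds_pos <= model$cds_len)
  widths <- model$cds$end - model$cds$start + 1L
  if (model$strand == "+") {
    ends <- cumsum(widths)
    i <- which(cds_pos <= ends)[1]
    off <- cds_pos - c(0L, ends)[i] - 1L
    as.integer(model$cds$start[i] + off)
  } else {
    # transcript order is rightmost interval first
    ord <- rev(seq_len(nrow(model$cds)))
    ends <- cumsum(widths[ord])
    k <- which(cds_pos <= ends)[1]
    i <- ord[k]
    off <- cds_pos - c(0L, ends)[k] - 1L
    as.integer(model$cds$end[i] - off)
  }
}

#' CDS coordinate of a genomic position, or NA when outside the CDS
#' @noRd
genomic_to_cds <- function(model, pos) {
  widths <- model$cds$end - model$cds$start + 1L
  hit <- which(pos >= model$cds$start & pos <= model$cds$end)
  if (length(hit) == 0) return(NA_integer_)
  if (model$strand == "+") {
    before <- if (hit > 1) sum(widths[seq_len(hit - 1)]) else 0L
    as.integer(before + (pos - model$cds$start[hit]) + 1L)
  } else {
    n <- nrow(model$cds)
    after <- if (hit < n) sum(widths[seq(hit + 1, n)]) else 0L
    as.integer(after + (model$cds$end[hit] - pos) + 1L)
  }
}
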