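# End-to-end orchestration: variants -> differential expression ->
# compensation -> expression bias, with TSV intermediates as the
# cross-stage contract and a single versioned JSON report.

REPORT_SCHEMA_VERSION <- "1.0"

#' Pipeline configuration
#'
#' @param counts,samples,variants,groups,gff,genome paths to the input
#'   files (TSV counts + sample sheet, VCF, group TSV, GFF3, FASTA). A
#'   fixture directory from [write_fixtures()] can be given instead via
#'   `fixture_dir`.
#' @param fixture_dir directory holding the standard fixture file names;
#'   individual path arguments override its entries.
#' @param ploidy_mode `"hexaploid"` or `"tetraploid"`.
#' @param alpha adjusted-p-value threshold (default 0.05).
#' @param yates apply the Yates correction in [compare_classes()]
#'   (default `TRUE`).
#' @param bias_min_tpm minimum summed WT group TPM for bias classification
#'   (default 0.5).
#' @param annotation consequence source, see [filter_mutations()].
#' @param wt_line wild-type genotype / VCF sample label (default `"WT"`).
#' @param out_dir output directory for per-stage TSVs and the JSON report
#'   (`NULL`: no files written).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts = NULL, samples = NULL, variants = NULL,
                            groups = NULL, gff = NULL, genome = NULL,
                            fixture_dir = NULL,
                            ploidy_mode = c("hexaploid", "tetraploid"),
                            alpha = 0.05, yates = TRUE, bias_min_tpm = 0.5,
                            annotation = "auto", wt_line = "WT",
                            out_dir = NULL) {
  ploidy_mode <- match.arg(ploidy_mode)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop_field("alpha", "must lie in (0, 1)")
  }
  defaults <- c(counts = "counts.tsv", samples = "samples.tsv",
                variants = "variants.vcf", groups = "groups.tsv",
                gff = "genes.gff3", genome = "genome.fa")
  paths <- list(counts = counts, samples = samples, variants = variants,
                groups = groups, gff = gff, genome = genome)
  for (nm in names(defaults)) {
    if (is.null(paths[[nm]]) && !is.null(fixture_dir)) {
      paths[[nm]] <- file.path(fixture_dir, defaults[[nm]])
    }
    if (is.null(paths[[nm]])) {
      stop_field(nm, "path must be given (directly or via fixture_dir)")
    }
    if (!file.exists(paths[[nm]])) {
      stop_field(nm, paste0("file not found: ", paths[[nm]]))
    }
  }
  structure(c(paths, list(ploidy_mode = ploidy_mode, alpha = alpha,
                          yates = yates, bias_min_tpm = bias_min_tpm,
                          annotation = annotation, wt_line = wt_line,
                          out_dir = out_dir)),
            class = "pipeline_config")
}

#' Run the full compensation pipeline
#'
#' Stages, aborting with the stage name on error: `variants` (consequence
#' calling + filtering cascade + group contexts), `diffexp` (NB Wald test
#' per mutant line vs WT), `compensation` (group calls, per-line and
#' pooled summaries, PTC-vs-synonymous chi-squared when both classes are
#' present) and `expression_bias` (WT bias categories). When
#' `config$out_dir` is set, per-stage TSVs and `report.json` are written
#' there.
#'
#' @param config a [pipeline_config()].
#' @return The report, a list with elements `schema_version`, `alpha`,
#'   `ploidy_mode`, `filter_counts`, `n_contexts`, `per_line`, `pooled`,
#'   `class_comparison` (or `NULL`), `bias_categories` and
#'   `n_not_evaluable`. The full intermediate objects are attached as
#'   attribute `"stages"`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  inputs <- stage("input", {
    list(cm = read_counts(config$counts, config$samples),
         variants = read_vcf(config$variants),
         groups = read_groups(config$groups),
         models = read_gene_models(config$gff),
         genome = read_genome(config$genome))
  })

  varstage <- stage("variants", {
    if (nrow(inputs$variants) == 0) {
      stop("variant table is empty", call. = FALSE)
    }
    asn <- filter_mutations(inputs$variants, inputs$groups, inputs$models,
                            genome = inputs$genome,
                            wt_line = config$wt_line,
                            annotation = config$annotation)
    list(assignments = asn, contexts = assign_groups(asn))
  })
  contexts <- varstage$contexts

  de <- stage("diffexp", {
    lines <- setdiff(unique(inputs$cm$samples$genotype), config$wt_line)
    do.call(rbind, lapply(lines, function(ln) {
      run_de(inputs$cm, line = ln, wt = config$wt_line,
             alpha = config$alpha)
    }))
  })

  comp <- stage("compensation", {
    calls <- call_groups(contexts, de, inputs$groups)
    summ <- summarize_compensation(calls)
    chi <- if (all(c("PTC", "synonymous") %in% summ$pooled$class)) {
      suppressWarnings(compare_classes(summ, correct = config$yates))
    } else NULL
    list(calls = calls, summary = summ, chi = chi)
  })

  bias <- stage("expression_bias", {
    lens <- vapply(inputs$models, `[[`, 0L, "cds_len")
    tpm <- tpm_from_counts(inputs$cm$counts, lens)
    wt_samples <- inputs$cm$samples$sample[
      inputs$cm$samples$genotype == config$wt_line]
    bv <- bias_vectors(inputs$groups, tpm, wt_samples,
                       min_tpm = config$bias_min_tpm)
    classify_bias_table(bv, config$ploidy_mode)
  })

  labels <- bias$label[!is.na(bias$label)]
  report <- list(
    schema_version = REPORT_SCHEMA_VERSION,
    ploidy_mode = config$ploidy_mode,
    alpha = config$alpha,
    filter_counts = as.list(attr(varstage$assignments, "filter_counts")),
    n_contexts = nrow(contexts),
    n_excluded_multimutant = nrow(attr(contexts, "excluded")),
    per_line = comp$summary$per_line,
    pooled = comp$summary$pooled,
    n_not_evaluable = comp$summary$n_not_evaluable,
    class_comparison = if (!is.null(comp$chi)) {
      list(statistic = comp$chi$statistic, df = comp$chi$df,
           p_value = comp$chi$p_value, corrected = comp$chi$corrected,
           table = as.data.frame(as.table(comp$chi$table)))
    },
    bias_categories = as.list(table(labels)))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    write_tsv(contexts, p("contexts.tsv"))
    write_de(de, p("de_results.tsv"))
    write_tsv(as.data.frame(comp$calls), p("compensation_calls.tsv"))
    write_tsv(comp$summary$per_line, p("summary_per_line.tsv"))
    write_tsv(comp$summary$pooled, p("summary_pooled.tsv"))
    write_tsv(bias, p("bias_categories.tsv"))
    jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  }
  attr(report, "stages") <- list(contexts = contexts, de = de,
                                 calls = comp$calls,
                                 summary = comp$summary, chi = comp$chi,
                                 bias = bias)
  report
}
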