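# Two-condition negative-binomial differential expression.
#
# Deliberately simple relative to the large DE frameworks: median-of-ratios
# size factors, method-of-moments gene dispersions shrunk halfway to a
# mean-dispersion trend, and a per-gene Wald test on the log fold change
# with plug-in dispersion. No Cox-Reid adjustment, no LFC shrinkage, no
# independent filtering — downstream decisions use only padj < alpha and
# the direction of the fold change, and calibration is checked by
# simulation rather than concordance with any particular package.

#' Assemble a count matrix with sample metadata
#'
#' @param counts integer matrix, genes in rows, samples in columns; row and
#'   column names required and unique.
#' @param samples data.frame with columns `sample`, `genotype`, `replicate`
#'   covering every column of `counts`.
#' @return A list of class `count_matrix` with elements `counts` and
#'   `samples` (reordered to match the matrix columns).
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene row names and sample column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids", call. = FALSE)
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  miss <- setdiff(colnames(counts), samples$sample)
  if (length(miss) > 0) {
    stop("sample(s) without metadata: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  samples <- samples[match(colnames(counts), samples$sample), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' Read counts TSV plus sample sheet
#' @param counts_path TSV, first column gene id, remaining columns samples.
#' @param samples_path TSV with columns `sample`, `genotype`, `replicate`.
#' @return A [count_matrix()].
#' @export
read_counts <- function(counts_path, samples_path) {
  df <- read_tsv(counts_path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  count_matrix(m, read_tsv(samples_path))
}

#' Write a count matrix and its sample sheet
#' @param cm a [count_matrix()].
#' @param counts_path,samples_path output paths.
#' @return `counts_path`, invisibly.
#' @export
write_counts <- function(cm, counts_path, samples_path) {
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, counts_path)
  write_tsv(cm$samples, samples_path)
  invisible(counts_path)
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over reference genes
#' (those with nonzero counts in every sample) of the ratio of the gene's
#' count to its geometric mean across samples.
#'
#' @param counts integer matrix or [count_matrix()].
#' @return Named numeric vector of per-sample size factors.
#' @export
estimate_size_factors <- function(counts) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref)) {
    stop("no gene has nonzero counts in all samples; consider a ",
         "pseudo-reference (e.g. add genes or pool samples)", call. = FALSE)
  }
  lg <- log(counts[ref, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(lg, 2, function(x) exp(median(x - geo)))
  setNames(sf, colnames(counts))
}

#' Per-gene dispersion with trend shrinkage
#'
#' Gene-wise method-of-moments estimates on normalized counts pooled
#' within conditions, `max(0, (s2 - mu)/mu^2)`, are shrunk toward a
#' `a0 + a1/mu` mean-dispersion trend (robustly fitted on the unfloored
#' estimates) with a fixed weight, and floored at a small positive
#' constant.
#'
#' @param counts integer matrix or [count_matrix()].
#' @param size_factors per-sample size factors.
#' @param condition factor/vector of condition labels per sample (taken
#'   from the `genotype` metadata when `counts` is a [count_matrix()]).
#' @param weight weight on the gene-wise estimate in the shrunk value
#'   (default 0.2). With 3 replicates per condition the gene-wise moment
#'   estimate has only 4 residual degrees of freedom; heavier weights
#'   propagate its sampling noise into the Wald standard errors and
#'   inflate the type-I error well beyond nominal (about 0.07 at weight
#'   0.5 in null simulations), so the default leans on the trend.
#' @param floor lower bound for the returned dispersions (default 1e-8).
#' @return Named numeric vector of per-gene dispersions alpha, where
#'   `Var = mu + alpha * mu^2`.
#' @export
estimate_dispersion <- function(counts, size_factors, condition = NULL,
                                weight = 0.2, floor = 1e-8) {
  if (inherits(counts, "count_matrix")) {
    if (is.null(condition)) condition <- counts$samples$genotype
    counts <- counts$counts
  }
  if (is.null(condition)) stop("`condition` is required", call. = FALSE)
  cond <- as.factor(condition)
  if (any(table(cond) < 2)) {
    stop("each condition needs >= 2 replicates for dispersion estimation",
         call. = FALSE)
  }
  norm <- sweep(counts, 2, size_factors, "/")
  mu <- rowMeans(norm)
  # pooled within-condition variance (Bessel-corrected per condition)
  ss <- 0
  df <- 0
  for (lv in levels(cond)) {
    x <- norm[, cond == lv, drop = FALSE]
    ctr <- x - rowMeans(x)
    ss <- ss + rowSums(ctr^2)
    df <- df + ncol(x) - 1
  }
  s2 <- ss / df
  raw <- ifelse(mu > 0, (s2 - mu) / mu^2, NA_real_)   # may be negative
  gene <- pmax(0, raw)

  # Trend fitted by least squares on the unfloored estimates: the raw
  # moment estimates are heavily right-skewed but mean-unbiased, so a
  # conditional-mean fit keeps the trend unbiased where a robust
  # (median-type) fit would sit below the true dispersion. One symmetric
  # trim of extreme standardized residuals guards against gross outliers.
  usable <- which(is.finite(raw) & mu > 0)
  trend <- rep(floor, length(mu))
  if (length(usable) >= 10) {
    x <- 1 / mu[usable]
    fit <- lm(raw[usable] ~ x)
    r <- residuals(fit)
    keep <- abs(r) <= 6 * sqrt(mean(r^2))
    if (any(!keep) && sum(keep) >= 10) fit <- lm(raw[usable][keep] ~ x[keep])
    co <- coef(fit)
    trend <- pmax(floor, co[1] + co[2] / mu)
  } else if (length(usable) > 0) {
    trend <- rep(max(floor, mean(raw[usable])), length(mu))
  }
  alpha <- pmax(floor, weight * gene + (1 - weight) * trend)
  alpha[!is.finite(alpha)] <- floor
  setNames(alpha, rownames(counts))
}

# Vectorised Newton solve of the per-group NB mean on the log scale:
# maximises sum_i logNB(y_i; mu_i = s_i * q, alpha) over beta = log(q).
# Returns list(beta, info) with info the Fisher information for beta.
nb_group_fit <- function(y, sf, alpha, floor_q) {
  tot <- rowSums(y)
  beta <- log(pmax(tot / sum(sf), floor_q))
  for (it in 1:50) {
    q <- exp(beta)
    mu <- outer(q, sf)
    denom <- 1 + alpha * mu
    score <- rowSums((y - mu) / denom)
    fisher <- rowSums(mu / denom)
    step <- score / pmax(fisher, 1e-12)
    step <- pmin(pmax(step, -2), 2)
    beta <- beta + step
    beta <- pmax(beta, log(floor_q))
    if (max(abs(step)) < 1e-10) break
  }
  q <- exp(beta)
  mu <- outer(q, sf)
  list(beta = beta, info = rowSums(mu / (1 + alpha * mu)))
}

#' Negative-binomial Wald test, mutant line versus wild type
#'
#' Fits per gene an NB model with a log link, per-sample size-factor
#' offsets and one mean per condition, then tests the log2 fold change
#' (mutant/WT) with a Wald statistic against the standard normal. Genes
#' with zero counts in every sample are reported with `NA` fold change and
#' p = 1 and are excluded from the BH adjustment.
#'
#' @param cm a [count_matrix()].
#' @param size_factors from [estimate_size_factors()].
#' @param dispersions from [estimate_dispersion()].
#' @param line mutant genotype label to contrast against `wt`.
#' @param wt wild-type genotype label (default `"WT"`).
#' @return A `data.frame` of class `de_result`: `gene_id`, `line`,
#'   `base_mean`, `fc` (linear, mutant/WT), `log2fc`, `se` (of log2fc),
#'   `pvalue`, `padj`, `status` (set by [classify_de()], initially
#'   `NA`).
#' @export
wald_test <- function(cm, size_factors, dispersions, line, wt = "WT") {
  geno <- cm$samples$genotype
  if (!wt %in% geno || !line %in% geno) {
    stop("genotype labels not found in sample metadata: ",
         paste(setdiff(c(wt, line), geno), collapse = ", "), call. = FALSE)
  }
  i_wt <- which(geno == wt)
  i_mut <- which(geno == line)
  if (length(i_wt) < 2 || length(i_mut) < 2) {
    stop("both conditions need >= 2 replicates", call. = FALSE)
  }
  y <- cm$counts
  alpha <- dispersions[rownames(y)]
  floor_q <- 0.5 / sum(size_factors[c(i_wt, i_mut)])
  all_zero <- rowSums(y[, c(i_wt, i_mut), drop = FALSE]) == 0

  fit_wt <- nb_group_fit(y[, i_wt, drop = FALSE], size_factors[i_wt],
                         alpha, floor_q)
  fit_mut <- nb_group_fit(y[, i_mut, drop = FALSE], size_factors[i_mut],
                          alpha, floor_q)
  log2fc <- (fit_mut$beta - fit_wt$beta) / log(2)
  se <- sqrt(1 / fit_mut$info + 1 / fit_wt$info) / log(2)
  z <- log2fc / se
  p <- 2 * pnorm(-abs(z))

  norm <- sweep(y[, c(i_wt, i_mut), drop = FALSE], 2,
                size_factors[c(i_wt, i_mut)], "/")
  res <- data.frame(gene_id = rownames(y), line = line,
                    base_mean = rowMeans(norm),
                    fc = 2^log2fc, log2fc = log2fc, se = se,
                    pvalue = p, padj = NA_real_, status = NA_character_,
                    stringsAsFactors = FALSE)
  res$fc[all_zero] <- NA_real_
  res$log2fc[all_zero] <- NA_real_
  res$se[all_zero] <- NA_real_
  res$pvalue[all_zero] <- 1
  res$padj[!all_zero] <- adjust_bh(res$pvalue[!all_zero])
  rownames(res) <- NULL
  class(res) <- c("de_result", "data.frame")
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues numeric vector in \[0, 1\] (`NA` allowed; passed
#'   through, not counted in `m`).
#' @return Adjusted p-values, same order as the input, capped at 1 and
#'   monotone over the sorted input.
#' @export
adjust_bh <- function(pvalues) {
  ok <- !is.na(pvalues)
  p <- pvalues[ok]
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  out <- rep(NA_real_, length(pvalues))
  if (m > 0) {
    o <- order(p, decreasing = TRUE)
    adj <- pmin(1, cummin(p[o] * m / seq(m, 1)))
    adj[o] <- adj
    out[ok] <- adj
  }
  out
}

#' Classify differential-expression status
#'
#' Upregulated when `padj < alpha` and fold change > 1; downregulated when
#' `padj < alpha` and fold change < 1; otherwise (including undefined fold
#' changes) no change.
#'
#' @param de a `de_result` data.frame from [wald_test()].
#' @param alpha adjusted-p-value threshold (default 0.05).
#' @return `de` with the `status` column filled with `"up"`, `"down"` or
#'   `"no_change"`.
#' @export
classify_de <- function(de, alpha = 0.05) {
  sig <- !is.na(de$padj) & de$padj < alpha & !is.na(de$fc)
  de$status <- "no_change"
  de$status[sig & de$fc > 1] <- "up"
  de$status[sig & de$fc < 1] <- "down"
  de
}

#' One-call differential expression for one mutant line
#'
#' Convenience wrapper: size factors, dispersions (on the WT + line subset),
#' Wald test, BH adjustment and status classification.
#'
#' @inheritParams wald_test
#' @param alpha threshold for [classify_de()].
#' @param dispersion_weight,dispersion_floor passed to
#'   [estimate_dispersion()].
#' @return A classified `de_result` data.frame.
#' @export
run_de <- function(cm, line, wt = "WT", alpha = 0.05,
                   dispersion_weight = 0.2, dispersion_floor = 1e-8) {
  keep <- cm$samples$genotype %in% c(wt, line)
  sub <- count_matrix(cm$counts[, cm$samples$sample[keep], drop = FALSE],
                      cm$samples[keep, , drop = FALSE])
  expressed <- rowSums(sub$counts) > 0
  sf <- estimate_size_factors(sub$counts[expressed, , drop = FALSE])
  disp <- estimate_dispersion(sub$counts, sf, sub$samples$genotype,
                              weight = dispersion_weight,
                              floor = dispersion_floor)
  classify_de(wald_test(sub, sf, disp, line = line, wt = wt), alpha = alpha)
}

#' Write DE results as TSV
#' @param de a `de_result` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_de <- function(de, path) write_tsv(de, path)
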