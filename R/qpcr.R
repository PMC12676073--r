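# RT-qPCR relative expression via the Pfaffl ratio and a one-way ANOVA
# genotype-effect test. Ct tables carry one row per (sample, target); the
# reference transcript (e.g. GAPDH) is measured in the same samples.

#' Efficiency-corrected relative expression (Pfaffl ratio)
#'
#' `ratio = E_target ^ dCt_target / E_ref ^ dCt_ref`, with
#' `dCt = mean Ct(calibrator) - Ct(sample)`.
#'
#' @param e_target,e_ref amplification efficiencies in (1, 2\].
#' @param dct_target,dct_ref delta-Ct values (calibrator mean minus
#'   sample).
#' @return The relative expression ratio.
#' @export
pfaffl_ratio <- function(e_target, dct_target, e_ref, dct_ref) {
  if (any(c(e_target, e_ref) <= 1) || any(c(e_target, e_ref) > 2)) {
    stop("primer efficiencies must lie in (1, 2]", call. = FALSE)
  }
  e_target^dct_target / e_ref^dct_ref
}

#' Pfaffl ratios for a Ct table
#'
#' Technical replicates (duplicate rows per sample and target) are
#' averaged to one Ct per biological sample before the ratio is formed.
#' The calibrator delta-Ct baseline is the mean Ct of `calibrator`
#' genotype samples, per target.
#'
#' @param ct data.frame with columns `sample`, `genotype`, `target`, `ct`,
#'   `efficiency`.
#' @param target target transcript name.
#' @param reference reference transcript name (e.g. `"GAPDH"`).
#' @param calibrator calibrator genotype (default `"WT"`).
#' @return A `data.frame`: `sample`, `genotype`, `ratio`.
#' @export
pfaffl_table <- function(ct, target, reference, calibrator = "WT") {
  need <- c("sample", "genotype", "target", "ct", "efficiency")
  if (!all(need %in% names(ct))) {
    stop("Ct table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  one <- function(tr) {
    d <- ct[ct$target == tr, , drop = FALSE]
    if (nrow(d) == 0) stop("no Ct rows for target ", tr, call. = FALSE)
    agg <- aggregate(ct ~ sample + genotype, data = d, FUN = mean)
    agg$efficiency <- d$efficiency[match(agg$sample, d$sample)]
    cal <- mean(agg$ct[agg$genotype == calibrator])
    if (!is.finite(cal)) {
      stop("no calibrator (", calibrator, ") samples for target ", tr,
           call. = FALSE)
    }
    agg$dct <- cal - agg$ct
    agg
  }
  tg <- one(target)
  rf <- one(reference)
  i <- match(tg$sample, rf$sample)
  if (anyNA(i)) {
    stop("sample(s) missing reference measurements: ",
         paste(tg$sample[is.na(i)], collapse = ", "), call. = FALSE)
  }
  data.frame(sample = tg$sample, genotype = tg$genotype,
             ratio = pfaffl_ratio(tg$efficiency, tg$dct,
                                  rf$efficiency[i], rf$dct[i]),
             stringsAsFactors = FALSE)
}

#' One-way ANOVA for a genotype effect on relative expression
#'
#' Fixed-effects linear model `ratio ~ genotype` followed by an F test.
#'
#' @param ratios data.frame with columns `genotype` and `ratio` (e.g. from
#'   [pfaffl_table()]).
#' @return A list with `f_statistic`, `df` (numerator, denominator) and
#'   `p_value`.
#' @export
genotype_effect_test <- function(ratios) {
  tab <- table(ratios$genotype)
  if (length(tab) < 2) stop("need >= 2 genotypes", call. = FALSE)
  if (any(tab < 2)) {
    stop("genotype(s) with < 2 replicates: ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  }
  fit <- lm(ratio ~ genotype, data = ratios)
  an <- anova(fit)
  list(f_statistic = an$`F value`[1],
       df = c(an$Df[1], an$Df[2]),
       p_value = an$`Pr(>F)`[1])
}
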