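# Group-level compensation calls and the PTC vs synonymous comparison.
#
# A (line, group) context is "compensated" when at least one NON-mutated
# homoeolog is significantly upregulated relative to wild type; the
# mutated homoeolog's own status never triggers the call.

#' Compensation calls for analyzable (line, group) contexts
#'
#' @param contexts output of [assign_groups()].
#' @param de classified DE results for the relevant lines, as one
#'   `de_result` data.frame (with a `line` column) or a list of them.
#' @param groups a [homoeolog_groups()] table.
#' @return A `data.frame` of class `compensation_calls`: `line`,
#'   `group_id`, `class`, `mutated_subgenome`, `mutated_gene`,
#'   `mutated_status`, `nonmut_statuses` (comma-separated, in subgenome
#'   order), `n_nonmut_up`, `compensated`, `evaluable`. Contexts whose
#'   mutated homoeolog has no DE result, or whose non-mutated homoeologs
#'   were all untested (zero expression), are flagged `evaluable = FALSE`
#'   with `compensated = NA`.
#' @export
call_groups <- function(contexts, de, groups) {
  if (is.list(de) && !is.data.frame(de)) de <- do.call(rbind, de)
  lookup <- group_lookup(groups)
  de_key <- paste(de$line, de$gene_id, sep = "\r")
  status_of <- function(line, gene) {
    i <- match(paste(line, gene, sep = "\r"), de_key)
    ifelse(is.na(i), NA_character_, de$status[i])
  }
  n <- nrow(contexts)
  out <- data.frame(line = contexts$line, group_id = contexts$group_id,
                    class = contexts$class,
                    mutated_subgenome = contexts$subgenome,
                    mutated_gene = contexts$gene_id,
                    mutated_status = NA_character_,
                    nonmut_statuses = NA_character_,
                    n_nonmut_up = NA_integer_,
                    compensated = NA, evaluable = NA,
                    stringsAsFactors = FALSE)
  lookup <- lookup[order(lookup$group_id, lookup$subgenome), , drop = FALSE]
  by_group <- split(seq_len(nrow(lookup)), lookup$group_id)
  for (i in seq_len(n)) {
    mem <- lookup[by_group[[contexts$group_id[i]]], , drop = FALSE]
    mut <- mem$subgenome == contexts$subgenome[i]
    out$mutated_status[i] <- status_of(contexts$line[i], mem$gene_id[mut])
    nm <- status_of(contexts$line[i], mem$gene_id[!mut])
    out$nonmut_statuses[i] <- paste(ifelse(is.na(nm), "untested", nm),
                                    collapse = ",")
    tested <- !is.na(nm)
    out$evaluable[i] <- !is.na(out$mutated_status[i]) && any(tested)
    if (out$evaluable[i]) {
      out$n_nonmut_up[i] <- sum(nm[tested] == "up")
      out$compensated[i] <- out$n_nonmut_up[i] >= 1L
    } else {
      hc_log("DEBUG", "call_groups: context (%s, %s) not evaluable",
             contexts$line[i], contexts$group_id[i])
    }
  }
  class(out) <- c("compensation_calls", "data.frame")
  out
}

#' Summarize compensation calls per line and pooled over unique groups
#'
#' Per-line proportions use that line's evaluable contexts as denominator.
#' The pooled ("headline") rate counts unique group ids: a group mutated in
#' several lines enters the denominator once and the numerator once if it
#' is compensated in at least one line.
#'
#' @param calls a `compensation_calls` data.frame from [call_groups()].
#' @return A list of class `compensation_summary` with elements
#'   `per_line` (line x class counts and percentages of mutated-homoeolog
#'   downregulation and of compensation), `pooled` (per class:
#'   `n_unique_groups`, `n_compensated`, `pct_compensated`) and
#'   `n_not_evaluable`.
#' @export
summarize_compensation <- function(calls) {
  if (nrow(calls) == 0) stop("no compensation calls to summarize", call. = FALSE)
  ev <- calls[!is.na(calls$evaluable) & calls$evaluable, , drop = FALSE]
  per_line <- do.call(rbind, lapply(
    split(ev, list(ev$line, ev$class), drop = TRUE), function(d) {
      data.frame(line = d$line[1], class = d$class[1],
                 n_contexts = nrow(d),
                 n_mut_down = sum(d$mutated_status == "down"),
                 pct_mut_down = 100 * mean(d$mutated_status == "down"),
                 n_compensated = sum(d$compensated),
                 pct_compensated = 100 * mean(d$compensated),
                 stringsAsFactors = FALSE)
    }))
  if (!is.null(per_line)) {
    per_line <- per_line[order(per_line$class, per_line$line), , drop = FALSE]
    rownames(per_line) <- NULL
  }
  pooled <- do.call(rbind, lapply(split(ev, ev$class), function(d) {
    comp_groups <- unique(d$group_id[d$compensated])
    data.frame(class = d$class[1],
               n_unique_groups = length(unique(d$group_id)),
               n_compensated = length(comp_groups),
               pct_compensated = 100 * length(comp_groups) /
                 length(unique(d$group_id)),
               stringsAsFactors = FALSE)
  }))
  rownames(pooled) <- NULL
  structure(list(per_line = per_line, pooled = pooled,
                 n_not_evaluable = sum(!calls$evaluable | is.na(calls$evaluable))),
            class = "compensation_summary")
}

#' @export
print.compensation_summary <- function(x, ...) {
  cat("Compensation summary\n\nPer line:\n")
  print(x$per_line, digits = 3)
  cat("\nPooled over unique groups:\n")
  print(x$pooled, digits = 3)
  if (x$n_not_evaluable > 0) {
    cat(sprintf("\n(%d context(s) not evaluable)\n", x$n_not_evaluable))
  }
  invisible(x)
}

#' Chi-squared comparison of PTC and synonymous compensation rates
#'
#' Pearson chi-squared test (df = 1) on the 2x2 table of compensated /
#' not-compensated unique groups by mutation class, with the Yates
#' continuity correction by default. A warning is emitted when any
#' expected cell count is below 5.
#'
#' @param summary a `compensation_summary`, or a 2x2 matrix with rows =
#'   classes and columns = (compensated, not compensated).
#' @param correct apply the Yates continuity correction (default `TRUE`).
#' @return A list with `statistic`, `df`, `p_value`, `table` and
#'   `corrected`.
#' @export
compare_classes <- function(summary, correct = TRUE) {
  if (inherits(summary, "compensation_summary")) {
    pl <- summary$pooled
    need <- c("PTC", "synonymous")
    if (!all(need %in% pl$class)) {
      stop("both mutation classes must have at least one group; missing: ",
           paste(setdiff(need, pl$class), collapse = ", "), call. = FALSE)
    }
    pl <- pl[match(need, pl$class), ]
    tab <- matrix(c(pl$n_compensated,
                    pl$n_unique_groups - pl$n_compensated),
                  nrow = 2, dimnames = list(class = need,
                                            c("compensated", "not")))
  } else {
    tab <- as.matrix(summary)
    if (!all(dim(tab) == c(2, 2))) stop("need a 2x2 table", call. = FALSE)
  }
  if (any(rowSums(tab) == 0)) {
    stop("a mutation class has zero groups", call. = FALSE)
  }
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  if (any(expected < 5)) {
    warning("expected cell count below 5; chi-squared approximation is poor",
            call. = FALSE)
  }
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  num <- abs(a * d - b * c_)
  if (correct) num <- max(0, num - n / 2)
  stat <- n * num^2 /
    (as.numeric(a + b) * (c_ + d) * (a + c_) * (b + d))
  if (!is.finite(stat)) stat <- 0  # a margin of zero: no evidence either way
  list(statistic = stat, df = 1L,
       p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       table = tab, corrected = correct)
}
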