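# Homoeolog expression-bias categories in wild type: each group's
# normalized homoeolog expression vector (TPM shares) is assigned to the
# nearest ideal pattern by Euclidean distance. Hexaploid triads use seven
# categories (balanced, one dominant or one suppressed subgenome);
# tetraploid dyads use three (balanced at 0.5:0.5, A or B dominant at 1:0).

#' Ideal bias points for a ploidy
#'
#' @param ploidy `"hexaploid"` (triads over A, B, D) or `"tetraploid"`
#'   (dyads over A, B).
#' @return Named list of ideal relative-expression vectors, in the fixed
#'   tie-break order: Balanced, then dominant (A, B, D), then suppressed
#'   (A, B, D).
#' @export
bias_ideal_points <- function(ploidy = c("hexaploid", "tetraploid")) {
  ploidy <- match.arg(ploidy)
  if (ploidy == "hexaploid") {
    sg <- c("A", "B", "D")
    pts <- list(Balanced = rep(1 / 3, 3))
    for (s in sg) {
      p <- setNames(rep(0, 3), sg); p[s] <- 1
      pts[[paste0(s, ".dominant")]] <- unname(p)
    }
    for (s in sg) {
      p <- setNames(rep(0.5, 3), sg); p[s] <- 0
      pts[[paste0(s, ".suppressed")]] <- unname(p)
    }
  } else {
    pts <- list(Balanced = c(0.5, 0.5),
                A.dominant = c(1, 0),
                B.dominant = c(0, 1))
  }
  pts
}

#' TPM from counts and effective lengths
#'
#' @param counts gene x sample matrix (or [count_matrix()]).
#' @param effective_lengths positive lengths, named by gene or in row
#'   order.
#' @return Matrix of transcripts per million; every column sums to 1e6
#'   (when any count is nonzero).
#' @export
tpm_from_counts <- function(counts, effective_lengths) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  if (!is.null(names(effective_lengths))) {
    effective_lengths <- effective_lengths[rownames(counts)]
  }
  if (any(!is.finite(effective_lengths)) || any(effective_lengths <= 0)) {
    stop("effective lengths must be positive for all genes", call. = FALSE)
  }
  rate <- counts / effective_lengths
  tot <- colSums(rate)
  tpm <- sweep(rate, 2, ifelse(tot > 0, tot, 1), "/") * 1e6
  tpm[, tot == 0] <- 0
  tpm
}

#' Relative homoeolog expression per group in wild type
#'
#' Mean TPM across the WT replicates per homoeolog, normalized to sum 1.
#' Groups whose summed mean TPM does not exceed `min_tpm` are marked not
#' classifiable (shares `NA`).
#'
#' @param groups a [homoeolog_groups()] table.
#' @param tpm TPM matrix from [tpm_from_counts()].
#' @param wt_samples column names of the WT replicates.
#' @param min_tpm minimum summed group TPM for classification
#'   (default 0.5).
#' @return A `data.frame`: `group_id`, `share_A`, `share_B`, `share_D`
#'   (`NA` column for dyads), `total_tpm`, `classifiable`.
#' @export
bias_vectors <- function(groups, tpm, wt_samples, min_tpm = 0.5) {
  missing <- setdiff(unlist(group_members(groups), use.names = FALSE),
                     rownames(tpm))
  if (length(missing) > 0) {
    stop("group member gene(s) absent from TPM matrix: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  wt_mean <- rowMeans(tpm[, wt_samples, drop = FALSE])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    m <- group_members(groups[i, , drop = FALSE])[[1]]
    v <- wt_mean[m]
    tot <- sum(v)
    ok <- tot > min_tpm
    share <- if (ok) v / tot else rep(NA_real_, length(v))
    data.frame(group_id = groups$group_id[i],
               share_A = share[1], share_B = share[2],
               share_D = if (length(v) == 3) share[3] else NA_real_,
               total_tpm = tot, classifiable = ok,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify one relative-expression vector
#'
#' @param shares numeric vector of length 3 (triad: A, B, D) or 2 (dyad:
#'   A, B) summing to 1.
#' @param ploidy `"hexaploid"` or `"tetraploid"`; default inferred from
#'   the length of `shares`.
#' @return A list with `label`, `distance` (to the chosen ideal point) and
#'   `tie` (`TRUE` when the minimum distance is attained by more than one
#'   ideal point; the label then follows the fixed order Balanced,
#'   dominant A/B/D, suppressed A/B/D).
#' @export
classify_bias <- function(shares, ploidy = NULL) {
  if (is.null(ploidy)) {
    ploidy <- if (length(shares) == 3) "hexaploid" else "tetraploid"
  }
  pts <- bias_ideal_points(ploidy)
  if (length(shares) != length(pts[[1]])) {
    stop(sprintf("expected a vector of length %d for %s groups, got %d",
                 length(pts[[1]]), ploidy, length(shares)), call. = FALSE)
  }
  if (any(!is.finite(shares)) || abs(sum(shares) - 1) > 1e-6) {
    stop("shares must be finite and sum to 1", call. = FALSE)
  }
  d <- vapply(pts, function(p) sqrt(sum((shares - p)^2)), numeric(1))
  best <- which.min(d)  # first index wins on exact ties: fixed order
  # ties are detected up to floating-point noise; genuinely distinct
  # categories are separated by far more than this
  list(label = names(pts)[best], distance = unname(d[best]),
       tie = sum(d - d[best] < 1e-9) > 1)
}

#' Bias categories for all classifiable groups
#'
#' @param vectors output of [bias_vectors()].
#' @param ploidy `"hexaploid"` or `"tetraploid"`.
#' @return `vectors` with added columns `label`, `distance`, `tie`
#'   (`NA` for non-classifiable groups).
#' @export
classify_bias_table <- function(vectors, ploidy = c("hexaploid", "tetraploid")) {
  ploidy <- match.arg(ploidy)
  k <- if (ploidy == "hexaploid") 3 else 2
  vectors$label <- NA_character_
  vectors$distance <- NA_real_
  vectors$tie <- NA
  for (i in which(vectors$classifiable)) {
    sh <- unlist(vectors[i, c("share_A", "share_B", "share_D")[seq_len(k)]])
    r <- classify_bias(unname(sh), ploidy)
    vectors$label[i] <- r$label
    vectors$distance[i] <- r$distance
    vectors$tie[i] <- r$tie
  }
  vectors
}
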