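#' ROC AUC for docking enrichment with failure censoring
#'
#' Computes the probability that a randomly chosen active is ranked better
#' (lower docking score) than a randomly chosen inactive, via the
#' Mann-Whitney rank formulation with midrank tie handling. A failed docking
#' (`NA` score) ranks strictly worse than every finite score; two failures
#' tie with each other and contribute 1/2, so a compound the engine could not
#' dock is never rewarded.
#'
#' Midranks make the antisymmetry identity exact:
#' `roc_auc(a, b)$auc + roc_auc(b, a)$auc == 1`.
#'
#' @param active_scores Numeric vector of active-ligand scores; `NA` = failed.
#' @param inactive_scores Numeric vector of inactive/decoy scores; `NA` = failed.
#' @return An object of class `roc_result`: list with `auc`, `n_actives`,
#'   `n_inactives`, `n_failed_actives`, `n_failed_inactives`.
#' @export
roc_auc <- function(active_scores, inactive_scores) {
  a <- as.numeric(active_scores)
  b <- as.numeric(inactive_scores)
  if (length(a) == 0) stop("need at least one active score")
  if (length(b) == 0) stop("need at least one inactive score")
  structure(
    list(auc = .auc_rank(a, b),
         n_actives = length(a),
         n_inactives = length(b),
         n_failed_actives = sum(is.na(a)),
         n_failed_inactives = sum(is.na(b))),
    class = "roc_result"
  )
}

# hot path shared with the exhaustive search: NA = failed -> +Inf sentinel,
# midranks via base rank(); lower score = better rank
.auc_rank <- function(a, b) {
  a[is.na(a)] <- Inf
  b[is.na(b)] <- Inf
  na <- length(a)
  r <- rank(c(a, b))
  u_worse <- sum(r[seq_len(na)]) - na * (na + 1) / 2  # active worse + ties/2
  N <- na * length(b)
  # single-division fraction form: (N - u)/N + u/N sums to 1 exactly, which
  # keeps the midrank antisymmetry identity bit-exact
  (N - u_worse) / N
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d actives, %d inactives; failed: %d / %d)\n",
              x$auc, x$n_actives, x$n_inactives,
              x$n_failed_actives, x$n_failed_inactives))
  invisible(x)
}

#' Per-class distribution of ensemble-aggregated docking scores
#'
#' Aggregates each ligand's score over the ensemble members (best score
#' across members, see [aggregate_scores()]) and summarises the resulting
#' per-class distributions: binned counts over the observed score range, the
#' fraction of ligands at or below a threshold (default -10.0 score units),
#' and the fraction that failed on every member. Failed ligands are excluded
#' from the score bins but counted in both denominators.
#'
#' @param matrix A `score_matrix`.
#' @param labels A `ligand_labels` object covering the matrix ligands.
#' @param members Conformation ids forming the ensemble; defaults to all.
#' @param threshold Score threshold for the at-or-below fraction.
#' @param binwidth Histogram bin width in score units.
#' @return An object of class `score_distribution`: list with `histogram`
#'   (data.frame class/bin_low/bin_high/count), `summary` (data.frame
#'   class/n/n_failed/frac_failed/frac_le_threshold) and `threshold`.
#' @export
score_distribution <- function(matrix, labels, members = NULL,
                               threshold = -10, binwidth = 1) {
  stopifnot(inherits(matrix, "score_matrix"), inherits(labels, "ligand_labels"))
  if (is.null(members)) members <- matrix$conformation_ids
  agg <- aggregate_scores(matrix, members)
  cls <- unclass(labels)[matrix$ligand_ids]
  if (any(is.na(cls))) stop("labels must cover all matrix ligands")
  classes <- intersect(.LIGAND_CLASSES, unique(cls))
  fin <- agg[!is.na(agg)]
  if (length(fin)) {
    lo <- floor(min(fin) / binwidth) * binwidth
    hi <- ceiling(max(fin) / binwidth) * binwidth
    if (hi <= lo) hi <- lo + binwidth
    breaks <- seq(lo, hi, by = binwidth)
  } else {
    breaks <- c(threshold - binwidth, threshold)
  }
  hist_rows <- list()
  summ_rows <- list()
  for (cl in classes) {
    v <- agg[cls == cl]
    n <- length(v)
    n_failed <- sum(is.na(v))
    vv <- v[!is.na(v)]
    cnt <- if (length(vv))
      as.vector(table(cut(vv, breaks = breaks, include.lowest = TRUE, right = TRUE)))
    else rep(0L, length(breaks) - 1L)
    hist_rows[[cl]] <- data.frame(
      class = cl,
      bin_low = breaks[-length(breaks)],
      bin_high = breaks[-1],
      count = cnt,
      stringsAsFactors = FALSE)
    summ_rows[[cl]] <- data.frame(
      class = cl, n = n, n_failed = n_failed,
      frac_failed = if (n) n_failed / n else NA_real_,
      frac_le_threshold = if (n) sum(vv <= threshold) / n else NA_real_,
      stringsAsFactors = FALSE)
  }
  structure(
    list(histogram = do.call(rbind, c(hist_rows, list(make.row.names = FALSE))),
         summary = do.call(rbind, c(summ_rows, list(make.row.names = FALSE))),
         threshold = threshold),
    class = "score_distribution"
  )
}

#' @export
print.score_distribution <- function(x, ...) {
  cat("<score_distribution>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write a score distribution histogram to CSV
#' @param x A `score_distribution` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_distribution <- function(x, path) {
  stopifnot(inherits(x, "score_distribution"))
  utils::write.csv(x$histogram, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
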