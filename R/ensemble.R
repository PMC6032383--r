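#' Ensemble selection objective
#'
#' `auc_vs_decoys` scores an ensemble by the ROC AUC of the active class
#' against the decoys. `summed_auc` adds a second term: the AUC of the active
#' class against another ligand class (e.g. antagonists vs agonists), both
#' terms weighted equally.
#'
#' @param kind `"auc_vs_decoys"` or `"summed_auc"`.
#' @param active_class Ligand class treated as active.
#' @param other_class Second reference class, required for `summed_auc`.
#' @return An object of class `ensemble_objective`.
#' @export
ensemble_objective <- function(kind = c("auc_vs_decoys", "summed_auc"),
                               active_class, other_class = NULL) {
  kind <- match.arg(kind)
  if (!active_class %in% .LIGAND_CLASSES)
    stop("unknown active_class: ", active_class)
  if (kind == "summed_auc") {
    if (is.null(other_class)) stop("summed_auc requires other_class")
    if (!other_class %in% .LIGAND_CLASSES)
      stop("unknown other_class: ", other_class)
    if (identical(other_class, active_class))
      stop("active_class and other_class must differ")
  } else {
    other_class <- NULL
  }
  structure(list(kind = kind, active_class = active_class,
                 other_class = other_class),
            class = "ensemble_objective")
}

.check_members <- function(matrix, members) {
  if (length(members) == 0) stop("'members' must be non-empty")
  if (anyDuplicated(members)) stop("'members' must be unique")
  unknown <- setdiff(members, matrix$conformation_ids)
  if (length(unknown))
    stop("unknown conformation id(s): ", paste(unknown, collapse = ", "))
  match(members, matrix$conformation_ids)
}

#' Aggregate per-ligand scores over an ensemble
#'
#' The ensemble-docking convention: a ligand's final score is its best
#' (minimum) score across the member conformations, ignoring failed cells.
#' The ligand is failed for the ensemble only if it failed on every member.
#'
#' @param matrix A `score_matrix`.
#' @param members Conformation ids forming the ensemble.
#' @return Named numeric vector (one entry per ligand); `NA` = failed on all
#'   members.
#' @export
aggregate_scores <- function(matrix, members) {
  stopifnot(inherits(matrix, "score_matrix"))
  idx <- .check_members(matrix, members)
  agg <- .agg_min(matrix$scores, idx)
  names(agg) <- matrix$ligand_ids
  agg
}

# min over member columns of an NA-coded score matrix; NA iff all NA
.agg_min <- function(smat, idx) {
  agg <- smat[, idx[1L]]
  for (j in idx[-1L]) agg <- pmin(agg, smat[, j], na.rm = TRUE)
  agg
}

.class_indices <- function(matrix, labels) {
  cls <- unclass(labels)[matrix$ligand_ids]
  if (any(is.na(cls)))
    stop("labels must cover all matrix ligands (use align_scores_labels first)")
  lapply(stats::setNames(nm = .LIGAND_CLASSES), function(cl) which(cls == cl))
}

.objective_values <- function(agg, ci, objective) {
  act <- ci[[objective$active_class]]
  dec <- ci[["decoy"]]
  if (length(act) == 0) stop("no ligands of class ", objective$active_class)
  if (length(dec) == 0) stop("no ligands of class decoy")
  v <- c(vs_decoys = .auc_rank(agg[act], agg[dec]))
  if (objective$kind == "summed_auc") {
    oth <- ci[[objective$other_class]]
    if (length(oth) == 0) stop("no ligands of class ", objective$other_class)
    v <- c(v, vs_other = .auc_rank(agg[act], agg[oth]))
  }
  v
}

#' Evaluate one ensemble under an objective
#'
#' Aggregates scores over the members ([aggregate_scores()]) and computes the
#' objective AUC value(s) with [roc_auc()] semantics (failure censoring,
#' midranks).
#'
#' @param matrix A `score_matrix`.
#' @param labels A `ligand_labels` object covering the matrix ligands.
#' @param members Conformation ids forming the ensemble.
#' @param objective An [ensemble_objective()].
#' @return An object of class `ensemble_result`: list with `members`,
#'   `aggregated`, `objective_values` (named AUCs), `objective_total`,
#'   `objective`.
#' @export
evaluate_ensemble <- function(matrix, labels, members, objective) {
  stopifnot(inherits(matrix, "score_matrix"),
            inherits(labels, "ligand_labels"),
            inherits(objective, "ensemble_objective"))
  .check_members(matrix, members)
  agg <- aggregate_scores(matrix, members)
  ci <- .class_indices(matrix, labels)
  v <- .objective_values(agg, ci, objective)
  structure(
    list(members = as.character(members), aggregated = agg,
         objective_values = v, objective_total = sum(v),
         objective = objective),
    class = "ensemble_result"
  )
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("<ensemble_result> {%s}\n", paste(x$members, collapse = ", ")))
  cat(sprintf("  objective (%s, active = %s%s): %s = %.4f\n",
              x$objective$kind, x$objective$active_class,
              if (!is.null(x$objective$other_class))
                paste0(", other = ", x$objective$other_class) else "",
              paste(sprintf("%s %.4f", names(x$objective_values),
                            x$objective_values), collapse = " + "),
              x$objective_total))
  invisible(x)
}

# deterministic tie-break key: sorted member ids joined; "\001" sorts before
# any printable character so shorter prefixes compare lexicographically
.member_key <- function(ids) paste(sort(ids), collapse = "\001")

#' Exhaustive best-subset ensemble search
#'
#' Evaluates all `choose(n, k)` size-`k` subsets of the conformation pool
#' under the objective and returns the global optimum plus the full ranked
#' candidate list. Ties on the objective total are broken deterministically
#' by the lexicographically smallest sorted member-id tuple.
#'
#' @param matrix A `score_matrix`.
#' @param labels A `ligand_labels` object covering the matrix ligands.
#' @param k Ensemble size (default 5, the conventional trade-off between
#'   conformational coverage and docking cost).
#' @param objective An [ensemble_objective()].
#' @return An object of class `ensemble_search`: list with `best` (an
#'   `ensemble_result`) and `candidates` (data.frame of all subsets ranked by
#'   descending objective total; members comma-joined).
#' @export
exhaustive_search <- function(matrix, labels, k = 5, objective) {
  stopifnot(inherits(matrix, "score_matrix"),
            inherits(labels, "ligand_labels"),
            inherits(objective, "ensemble_objective"))
  n <- length(matrix$conformation_ids)
  if (!(k >= 1 && k <= n)) stop("k must satisfy 1 <= k <= ", n)
  ci <- .class_indices(matrix, labels)
  subsets <- utils::combn(n, k)
  smat <- matrix$scores
  ids <- matrix$conformation_ids
  m <- ncol(subsets)
  nterm <- if (objective$kind == "summed_auc") 2L else 1L
  vals <- matrix(NA_real_, nrow = m, ncol = nterm)
  for (s in seq_len(m)) {
    agg <- .agg_min(smat, subsets[, s])
    vals[s, ] <- .objective_values(agg, ci, objective)
  }
  totals <- rowSums(vals)
  keys <- vapply(seq_len(m), function(s) .member_key(ids[subsets[, s]]),
                 character(1))
  ord <- order(-totals, keys)
  member_str <- vapply(seq_len(m), function(s)
    paste(sort(ids[subsets[, s]]), collapse = ","), character(1))
  candidates <- data.frame(
    rank = seq_len(m),
    members = member_str[ord],
    auc_vs_decoys = vals[ord, 1L],
    stringsAsFactors = FALSE)
  if (nterm == 2L) candidates$auc_vs_other <- vals[ord, 2L]
  candidates$objective_total <- totals[ord]
  best_members <- sort(ids[subsets[, ord[1L]]])
  best <- evaluate_ensemble(matrix, labels, best_members, objective)
  structure(list(best = best, candidates = candidates, k = k,
                 objective = objective),
            class = "ensemble_search")
}

#' @export
print.ensemble_search <- function(x, ...) {
  cat(sprintf("<ensemble_search> k = %d, %d candidates evaluated\n",
              x$k, nrow(x$candidates)))
  print(x$best)
  invisible(x)
}
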