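#' Cross-docking report: is each ligand's best score on its native structure?
#'
#' For a cross-docking score matrix (each ligand docked into every receptor
#' conformation) and a ligand-to-native-structure map, reports per ligand the
#' best-scoring conformation, whether it coincides with the native one, and
#' the failure counts.
#'
#' @param matrix A `score_matrix`.
#' @param native_map Named character vector: ligand id -> native conformation
#'   id. Defaults to the identity map on the shared ids (the usual layout of
#'   a cross-docking table).
#' @return An object of class `crossdock_report`: list with `per_ligand`
#'   (data.frame), `n_native_best`, `n_ligands`, `n_failed_cells`.
#' @export
run_crossdock_report <- function(matrix, native_map = NULL) {
  stopifnot(inherits(matrix, "score_matrix"))
  if (is.null(native_map))
    native_map <- stats::setNames(matrix$ligand_ids, matrix$ligand_ids)
  miss <- setdiff(names(native_map), matrix$ligand_ids)
  if (length(miss))
    stop("native map names unknown ligand(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unname(native_map), matrix$conformation_ids)
  if (length(bad))
    stop("native conformation id(s) missing from matrix: ",
         paste(bad, collapse = ", "))
  ligs <- intersect(matrix$ligand_ids, names(native_map))
  if (length(ligs) == 0) stop("native map covers no matrix ligand")
  s <- matrix$scores[ligs, , drop = FALSE]
  rows <- lapply(ligs, function(l) {
    v <- s[l, ]
    n_failed <- sum(is.na(v))
    if (all(is.na(v))) {
      best <- NA_character_
      best_score <- NA_real_
    } else {
      best <- matrix$conformation_ids[which.min(v)]
      best_score <- min(v, na.rm = TRUE)
    }
    data.frame(ligand_id = l, best_conformation = best,
               best_score = best_score,
               native_conformation = unname(native_map[l]),
               native_best = identical(best, unname(native_map[l])),
               n_failed = n_failed, stringsAsFactors = FALSE)
  })
  per_ligand <- do.call(rbind, rows)
  structure(
    list(per_ligand = per_ligand,
         n_native_best = sum(per_ligand$native_best),
         n_ligands = length(ligs),
         n_failed_cells = sum(matrix$failed[ligs, , drop = FALSE])),
    class = "crossdock_report"
  )
}

#' @export
print.crossdock_report <- function(x, ...) {
  cat(sprintf("<crossdock_report> %d / %d ligand(s) best on their native structure; %d failed cell(s)\n",
              x$n_native_best, x$n_ligands, x$n_failed_cells))
  not_native <- x$per_ligand$ligand_id[!x$per_ligand$native_best]
  if (length(not_native))
    cat("  non-native best:", paste(not_native, collapse = ", "), "\n")
  invisible(x)
}

.stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  message(sprintf("[%s] done in %.2f s", name, proc.time()[["elapsed"]] - t0))
  out
}

#' End-to-end ensemble screening benchmark
#'
#' Reproduces the screening workflow shape: load (or simulate) a score
#' matrix and labels, exhaustively select the best size-`k` ensembles for
#' each objective (antagonist-vs-decoy, agonist-vs-decoy, and both summed
#' objectives for class discrimination), cross-evaluate every selected
#' ensemble against every active/inactive pairing into a long-format AUC
#' table (columns ensemble/auc/actives/decoys), and write per-ensemble score
#' distributions. Each stage error is re-signalled with its stage name.
#'
#' @param config List with either `scores` + `labels` (CSV paths) or `sim`
#'   (a [score_gen_config()]); optional `k` (default 5), `threshold`
#'   (default -10), `out_dir` (results are written there when given).
#' @return A report bundle (list) with elements `selected` (named list of
#'   `ensemble_result`s), `auc_table`, `distributions`, `decision_log`.
#' @export
run_full_benchmark <- function(config) {
  k <- if (is.null(config$k)) 5 else config$k
  threshold <- if (is.null(config$threshold)) -10 else config$threshold
  log <- character(0)

  inputs <- .stage("load", {
    if (!is.null(config$sim)) {
      stopifnot(inherits(config$sim, "score_gen_config"))
      g <- gen_score_matrix(config$sim)
      list(matrix = g$matrix, labels = g$labels)
    } else {
      if (is.null(config$scores) || is.null(config$labels))
        stop("config needs either 'sim' or both 'scores' and 'labels'")
      m <- load_score_matrix(config$scores)
      l <- load_labels(config$labels)
      withCallingHandlers(
        align_scores_labels(m, l),
        warning = function(w) {
          log <<- c(log, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
    }
  })
  m <- inputs$matrix
  l <- inputs$labels

  objectives <- list(
    antagonist_vs_decoys = ensemble_objective("auc_vs_decoys", "antagonist"),
    agonist_vs_decoys = ensemble_objective("auc_vs_decoys", "agonist"),
    antagonist_summed = ensemble_objective("summed_auc", "antagonist", "agonist"),
    agonist_summed = ensemble_objective("summed_auc", "agonist", "antagonist"))

  selected <- .stage("select", {
    out <- list()
    for (nm in names(objectives)) {
      sr <- exhaustive_search(m, l, k = k, objective = objectives[[nm]])
      top <- sr$candidates$objective_total[1]
      n_tied <- sum(abs(sr$candidates$objective_total - top) < .Machine$double.eps)
      if (n_tied > 1)
        log <- c(log, sprintf(
          "%s: %d candidates tied at the optimum; lexicographic tie-break applied",
          nm, n_tied))
      out[[nm]] <- sr$best
    }
    out
  })

  auc_table <- .stage("evaluate", {
    rows <- list()
    pairings <- list(c("antagonist", "decoy"), c("antagonist", "agonist"),
                     c("agonist", "decoy"), c("agonist", "antagonist"))
    for (nm in names(selected)) {
      agg <- selected[[nm]]$aggregated
      ci <- .class_indices(m, l)
      for (p in pairings) {
        if (length(ci[[p[1]]]) == 0 || length(ci[[p[2]]]) == 0) next
        rows[[length(rows) + 1L]] <- data.frame(
          ensemble = nm,
          auc = .auc_rank(agg[ci[[p[1]]]], agg[ci[[p[2]]]]),
          actives = p[1], decoys = p[2], stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })

  distributions <- .stage("distributions", {
    lapply(selected, function(res)
      score_distribution(m, l, members = res$members, threshold = threshold))
  })

  bundle <- list(selected = selected, auc_table = auc_table,
                 distributions = distributions, decision_log = log,
                 k = k, matrix = m, labels = l)

  if (!is.null(config$out_dir)) {
    .stage("write", {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(auc_table, file.path(config$out_dir, "auc_table.csv"),
                       row.names = FALSE, quote = FALSE)
      for (nm in names(selected)) {
        jsonlite::write_json(
          list(members = selected[[nm]]$members,
               objective_values = as.list(selected[[nm]]$objective_values),
               objective_total = selected[[nm]]$objective_total),
          file.path(config$out_dir, paste0("ensemble_", nm, ".json")),
          auto_unbox = TRUE, digits = NA)
        write_score_distribution(
          distributions[[nm]],
          file.path(config$out_dir, paste0("distribution_", nm, ".csv")))
      }
      writeLines(log, file.path(config$out_dir, "decision_log.txt"))
    })
  }
  bundle
}

#' Bundled cross-docking example
#'
#' Loads the packaged 5x5 cross-docking example (five steroid-pocket
#' ligands docked into five receptor crystal conformations, with N/A cells
#' where docking produced no pose) together with its native-structure map
#' and labels.
#'
#' @return List with `matrix` (a `score_matrix`), `native_map` (named
#'   character vector) and `labels` (a `ligand_labels`).
#' @export
load_crossdock_example <- function() {
  ext <- system.file("extdata", package = "ensdock")
  nm <- utils::read.csv(file.path(ext, "crossdock_native_map.csv"),
                        colClasses = "character")
  list(
    matrix = load_score_matrix(file.path(ext, "crossdock_scores.csv")),
    native_map = stats::setNames(nm[[2]], nm[[1]]),
    labels = load_labels(file.path(ext, "crossdock_labels.csv"))
  )
}
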