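#' Docking score matrix with per-cell failure flags
#'
#' The central exchange object of the package: a ligands x conformations grid
#' of docking scores (lower = more favourable, the usual empirical
#' docking-score sign convention) together
#' with a logical grid marking cells where the docking engine returned no pose.
#' A failed cell carries no score; internally its score slot is `NA` and is
#' never the sentinel 0, so a legitimate score of 0.0 cannot collide with a
#' failure.
#'
#' @param scores Numeric matrix with unique row names (ligand ids) and unique
#'   column names (conformation ids). `NA` cells are taken as failures unless
#'   `failed` is supplied.
#' @param failed Optional logical matrix of the same shape; `TRUE` marks a
#'   docking failure. Defaults to `is.na(scores)`.
#' @return An object of class `score_matrix` with elements `scores`, `failed`,
#'   `ligand_ids` and `conformation_ids`.
#' @export
score_matrix <- function(scores, failed = NULL) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  if (is.null(failed)) failed <- is.na(scores)
  failed <- as.matrix(failed)
  storage.mode(failed) <- "logical"
  if (!identical(dim(scores), dim(failed)))
    stop("'scores' and 'failed' must have identical dimensions")
  lig <- rownames(scores)
  conf <- colnames(scores)
  if (is.null(lig) || is.null(conf))
    stop("'scores' must have row names (ligand ids) and column names (conformation ids)")
  if (anyDuplicated(lig))
    stop("duplicate ligand id(s): ", paste(unique(lig[duplicated(lig)]), collapse = ", "))
  if (anyDuplicated(conf))
    stop("duplicate conformation id(s): ", paste(unique(conf[duplicated(conf)]), collapse = ", "))
  if (any(is.na(failed)))
    stop("'failed' must not contain NA")
  scores[failed] <- NA_real_
  ok <- !failed
  if (any(ok & (is.na(scores) | !is.finite(scores))))
    stop("non-failed cells must hold finite scores")
  dimnames(failed) <- dimnames(scores)
  structure(
    list(scores = scores, failed = failed,
         ligand_ids = lig, conformation_ids = conf),
    class = "score_matrix"
  )
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix> %d ligands x %d conformations, %d failed cell(s)\n",
              length(x$ligand_ids), length(x$conformation_ids), sum(x$failed)))
  invisible(x)
}

#' @export
dim.score_matrix <- function(x) dim(x$scores)

#' Scores with failures coded as NA
#'
#' @param x A `score_matrix`.
#' @return Numeric matrix; failed cells are `NA`.
#' @export
scores_na <- function(x) {
  stopifnot(inherits(x, "score_matrix"))
  x$scores
}

.FAIL_TOKENS <- c("NA", "N/A", "")

.parse_score_cell <- function(cell) {
  if (is.na(cell)) return(NA_real_)  # read.csv maps a literal NA token here
  # normalise the typographic minus/dashes that PDF-extracted tables carry
  cell <- trimws(gsub("[−–—]", "-", cell))
  if (toupper(cell) %in% .FAIL_TOKENS) return(NA_real_)
  val <- suppressWarnings(as.numeric(cell))
  if (is.na(val)) return(NaN)  # marker: unparseable, distinct from failure
  val
}

#' Read a docking score matrix from CSV
#'
#' Expected layout: header `ligand_id,<conf1>,<conf2>,...`; one row per
#' ligand; cells are decimal scores or a failure token (`NA`, `N/A`, or an
#' empty cell). Unicode minus signs are normalised to ASCII on read.
#'
#' @param path Path to the CSV file.
#' @return A validated [score_matrix()].
#' @export
load_score_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         strip.white = TRUE)
  if (ncol(raw) < 2) stop("score CSV needs a ligand id column plus >= 1 conformation column")
  lig <- raw[[1]]
  conf <- colnames(raw)[-1]
  if (anyDuplicated(lig))
    stop("duplicate ligand id(s) in ", path, ": ",
         paste(unique(lig[duplicated(lig)]), collapse = ", "))
  if (anyDuplicated(conf))
    stop("duplicate conformation id(s) in ", path, ": ",
         paste(unique(conf[duplicated(conf)]), collapse = ", "))
  m <- matrix(NA_real_, nrow = nrow(raw), ncol = length(conf),
              dimnames = list(lig, conf))
  for (j in seq_along(conf)) {
    vals <- vapply(raw[[j + 1L]], .parse_score_cell, numeric(1), USE.NAMES = FALSE)
    bad <- which(is.nan(vals))
    if (length(bad))
      stop(sprintf("non-numeric cell at ligand '%s', conformation '%s' in %s",
                   lig[bad[1L]], conf[j], path))
    m[, j] <- vals
  }
  score_matrix(m)
}

#' Write a score matrix to CSV
#'
#' Failed cells are written as the token `NA`. [load_score_matrix()] on the
#' written file reproduces the object exactly.
#'
#' @param x A `score_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_matrix <- function(x, path) {
  stopifnot(inherits(x, "score_matrix"))
  df <- data.frame(ligand_id = x$ligand_ids, x$scores,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "NA", quote = FALSE)
  invisible(path)
}

.LIGAND_CLASSES <- c("agonist", "antagonist", "decoy")

#' Ligand class labels
#'
#' @param ids Character vector of ligand ids (unique), or a named character
#'   vector of classes (names = ids) with `classes` missing.
#' @param classes Character vector of class tags, each one of `"agonist"`,
#'   `"antagonist"`, `"decoy"`.
#' @return A named character vector of class `ligand_labels`.
#' @export
ligand_labels <- function(ids, classes = NULL) {
  if (is.null(classes)) {
    classes <- unname(ids)
    ids <- names(ids)
    if (is.null(ids) && length(classes) > 0)
      stop("single-argument form requires a named vector")
    if (is.null(ids)) ids <- character(0)
  }
  ids <- as.character(ids)
  classes <- as.character(classes)
  if (length(ids) != length(classes)) stop("ids and classes differ in length")
  if (anyDuplicated(ids))
    stop("duplicate ligand id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  bad <- setdiff(unique(classes), .LIGAND_CLASSES)
  if (length(bad))
    stop("unknown class token(s): ", paste(bad, collapse = ", "),
         " (valid: ", paste(.LIGAND_CLASSES, collapse = ", "), ")")
  structure(stats::setNames(classes, ids), class = "ligand_labels")
}

#' @export
print.ligand_labels <- function(x, ...) {
  tab <- table(factor(unclass(x), levels = .LIGAND_CLASSES))
  cat(sprintf("<ligand_labels> %d ligands (%s)\n", length(x),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Read ligand class labels from CSV
#'
#' Expected layout: two columns, `ligand_id,class`, with class one of
#' agonist/antagonist/decoy. An empty file (header only) yields an empty,
#' valid mapping.
#'
#' @param path Path to the CSV file.
#' @return A [ligand_labels()] object.
#' @export
load_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         strip.white = TRUE)
  if (ncol(raw) < 2) stop("label CSV needs columns: ligand_id, class")
  ligand_labels(raw[[1]], raw[[2]])
}

#' Write ligand labels to CSV
#' @param x A `ligand_labels` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(x, path) {
  stopifnot(inherits(x, "ligand_labels"))
  utils::write.csv(
    data.frame(ligand_id = names(x), class = unclass(unname(x)),
               stringsAsFactors = FALSE),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Restrict a score matrix and label set to their common ligands
#'
#' Keeps the intersection of ligand ids, preserving the matrix row order.
#' Ids present on only one side are dropped with a warning.
#'
#' @param matrix A `score_matrix`.
#' @param labels A `ligand_labels` object.
#' @return A list with elements `matrix` and `labels`, aligned.
#' @export
align_scores_labels <- function(matrix, labels) {
  stopifnot(inherits(matrix, "score_matrix"), inherits(labels, "ligand_labels"))
  common <- intersect(matrix$ligand_ids, names(labels))
  if (length(common) == 0)
    stop("no ligand ids shared between score matrix and labels")
  drop_m <- setdiff(matrix$ligand_ids, common)
  drop_l <- setdiff(names(labels), common)
  if (length(drop_m))
    warning(length(drop_m), " unlabelled ligand(s) dropped from score matrix: ",
            paste(utils::head(drop_m, 5), collapse = ", "),
            if (length(drop_m) > 5) ", ...")
  if (length(drop_l))
    warning(length(drop_l), " label(s) without scores dropped: ",
            paste(utils::head(drop_l, 5), collapse = ", "),
            if (length(drop_l) > 5) ", ...")
  keep <- matrix$ligand_ids[matrix$ligand_ids %in% common]
  out_m <- score_matrix(matrix$scores[keep, , drop = FALSE],
                        matrix$failed[keep, , drop = FALSE])
  out_l <- ligand_labels(keep, unclass(labels)[keep])
  list(matrix = out_m, labels = out_l)
}
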