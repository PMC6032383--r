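# Independent oracles and fixture builders, deliberately coded in the most
# naive way possible (explicit loops, no ranks) so they share nothing with
# the implementation paths they check.

# Pairwise-counting AUC: win = 1, tie = 1/2, failure (NA) worse than any
# finite score, two failures tie.
oracle_auc <- function(active, inactive) {
  wins <- 0
  for (x in active) {
    for (y in inactive) {
      xx <- if (is.na(x)) Inf else x
      yy <- if (is.na(y)) Inf else y
      if (xx < yy) wins <- wins + 1
      else if (xx == yy) wins <- wins + 0.5
    }
  }
  wins / (length(active) * length(inactive))
}

# Naive enumeration of all size-k member subsets with loop-based min
# aggregation; ties broken by the lexicographically smallest sorted id tuple.
oracle_exhaustive <- function(scores, failed, classes, k, active_class) {
  conf_ids <- colnames(scores)
  subsets <- utils::combn(conf_ids, k, simplify = FALSE)
  best <- NULL
  best_auc <- -Inf
  best_key <- NULL
  act <- which(classes == active_class)
  dec <- which(classes == "decoy")
  for (memb in subsets) {
    agg <- rep(NA_real_, nrow(scores))
    for (i in seq_len(nrow(scores))) {
      vals <- c()
      for (cid in memb)
        if (!failed[i, cid]) vals <- c(vals, scores[i, cid])
      if (length(vals)) agg[i] <- min(vals)
    }
    auc <- oracle_auc(agg[act], agg[dec])
    key <- paste(sort(memb), collapse = "\001")
    if (auc > best_auc || (auc == best_auc && key < best_key)) {
      best_auc <- auc
      best <- sort(memb)
      best_key <- key
    }
  }
  list(members = best, auc = best_auc)
}

# A frame_set wrapping bare protein coordinates (no ligand), for cavity
# fixtures.
make_protein_frame <- function(coords, element = "C") {
  n <- nrow(coords)
  atoms <- data.frame(
    atom_id = seq_len(n), name = "C", element = element,
    resno = seq_len(n), resname = "ALA", chain = "A", is_ligand = FALSE,
    stringsAsFactors = FALSE)
  frame_set(atoms, list(coords))
}

# Closed cubic shell of atoms: faces at +/- half on each axis, lattice
# spacing ~1 A (exact endpoint inclusion so the shell is sealed).
cube_shell <- function(half = 6.1, spacing = 1) {
  g <- seq(-half, half, length.out = round(2 * half / spacing) + 1)
  pts <- as.matrix(expand.grid(g, g, g))
  on_face <- abs(abs(pts[, 1]) - half) < 1e-9 |
    abs(abs(pts[, 2]) - half) < 1e-9 |
    abs(abs(pts[, 3]) - half) < 1e-9
  unname(pts[on_face, , drop = FALSE])
}

# Spherical shell of n atoms at radius r (Fibonacci lattice).
sphere_shell <- function(n = 1000, r = 7.1) {
  gold <- pi * (3 - sqrt(5))
  k <- seq_len(n)
  z <- 1 - (2 * k - 1) / n
  rho <- sqrt(pmax(0, 1 - z^2))
  r * cbind(rho * cos(gold * k), rho * sin(gold * k), z)
}

# Random score_matrix + labels for property tests.
random_screen <- function(n_lig, n_conf, fail_p = 0.2,
                          classes = NULL) {
  lig <- sprintf("L%02d", seq_len(n_lig))
  conf <- sprintf("c%02d", seq_len(n_conf))
  s <- matrix(round(stats::rnorm(n_lig * n_conf, -8, 3), 1),
              n_lig, n_conf, dimnames = list(lig, conf))
  f <- matrix(stats::runif(n_lig * n_conf) < fail_p, n_lig, n_conf)
  s[f] <- NA
  if (is.null(classes)) {
    classes <- sample(c("agonist", "antagonist", "decoy"), n_lig,
                      replace = TRUE)
    # guarantee each class present
    classes[1:3] <- c("agonist", "antagonist", "decoy")
  }
  list(matrix = score_matrix(s, f), labels = ligand_labels(lig, classes),
       classes = classes)
}

# Partition equality up to label permutation.
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(apply(table(a, b) > 0, 1, sum) == 1) &&
    all(apply(table(a, b) > 0, 2, sum) == 1)
}
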