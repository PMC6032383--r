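#' Frame set: coordinate snapshots over a fixed atom table
#'
#' Holds an ordered collection of 3D coordinate frames (Angstrom) sharing one
#' atom table — e.g. snapshots of a trajectory, or a single crystal
#' structure. The atom table flags which atoms belong to the bound ligand;
#' the ligand defines the binding site.
#'
#' @param atoms data.frame with columns `atom_id` (unique), `name` (PDB atom
#'   name), `element`, `resno`, `resname`, `chain`, `is_ligand` (logical).
#' @param frames List of numeric n_atoms x 3 coordinate matrices.
#' @return An object of class `frame_set`.
#' @export
frame_set <- function(atoms, frames) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("atom_id", "name", "element", "resno", "resname", "chain", "is_ligand")
  miss <- setdiff(need, colnames(atoms))
  if (length(miss)) stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(atoms$atom_id)) stop("atom ids must be unique")
  if (!is.list(frames) || length(frames) == 0) stop("need >= 1 coordinate frame")
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    storage.mode(f) <- "double"
    if (ncol(f) != 3 || nrow(f) != nrow(atoms))
      stop("each frame must be an n_atoms x 3 matrix")
    if (!all(is.finite(f))) stop("coordinates must be finite")
    dimnames(f) <- NULL
    f
  })
  structure(list(atoms = atoms, frames = frames), class = "frame_set")
}

#' @export
print.frame_set <- function(x, ...) {
  cat(sprintf("<frame_set> %d frame(s), %d atoms (%d ligand)\n",
              length(x$frames), nrow(x$atoms), sum(x$atoms$is_ligand)))
  invisible(x)
}

#' Number of frames in a frame set
#' @param x A `frame_set`.
#' @return Integer frame count.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "frame_set"))
  length(x$frames)
}

.element_from_pdb <- function(elesy, elety) {
  el <- toupper(trimws(as.character(elesy)))
  fallback <- toupper(sub("^[0-9']*([A-Za-z]).*$", "\\1", trimws(elety)))
  bad <- is.na(el) | el == ""
  el[bad] <- fallback[bad]
  # two-letter symbols keep case convention H/C/N/O/S single letter
  substr(el, 1, 1) <- toupper(substr(el, 1, 1))
  el
}

.read_one_pdb <- function(path, ligand_resname) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  # altloc: keep the highest-occupancy record per (chain, resno, insert, name)
  alt <- at$alt
  if (any(!is.na(alt) & alt != "")) {
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\001")
    occ <- at$o
    occ[is.na(occ)] <- 1
    ord <- order(key, -occ)
    keep <- sort(ord[!duplicated(key[ord])])
    at <- at[keep, , drop = FALSE]
    xyz <- xyz[, as.vector(rbind(3 * keep - 2, 3 * keep - 1, 3 * keep)),
               drop = FALSE]
  }
  n <- nrow(at)
  atoms <- data.frame(
    atom_id = seq_len(n),
    name = trimws(at$elety),
    element = .element_from_pdb(at$elesy, at$elety),
    resno = at$resno,
    resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain), "A", at$chain),
    is_ligand = trimws(at$resid) == ligand_resname,
    stringsAsFactors = FALSE)
  frames <- lapply(seq_len(nrow(xyz)), function(i)
    matrix(xyz[i, ], ncol = 3, byrow = TRUE))
  list(atoms = atoms, frames = frames)
}

#' Read coordinate frames from PDB files
#'
#' Accepts one or more single- or multi-MODEL PDB files with identical atom
#' composition; all models are concatenated into one frame set. Alternate
#' locations are resolved by keeping the highest-occupancy record.
#'
#' @param paths Character vector of PDB file paths.
#' @param ligand_resname Residue name identifying the bound ligand.
#' @return A [frame_set()].
#' @export
read_frames <- function(paths, ligand_resname) {
  if (length(paths) == 0) stop("need >= 1 PDB path")
  parsed <- lapply(paths, .read_one_pdb, ligand_resname = ligand_resname)
  n0 <- nrow(parsed[[1]]$atoms)
  for (i in seq_along(parsed)) {
    if (nrow(parsed[[i]]$atoms) != n0)
      stop(sprintf("atom count mismatch: %s has %d atoms, %s has %d",
                   paths[1], n0, paths[i], nrow(parsed[[i]]$atoms)))
  }
  atoms <- parsed[[1]]$atoms
  if (!any(atoms$is_ligand))
    stop("no atoms with ligand residue name '", ligand_resname, "'")
  frame_set(atoms, unlist(lapply(parsed, `[[`, "frames"), recursive = FALSE))
}

#' Write a frame set as a (multi-MODEL) PDB file
#'
#' Frames are written as consecutive MODEL/ENDMDL blocks (a single frame is
#' written as a plain PDB). Round-trips through [read_frames()].
#'
#' @param x A `frame_set`.
#' @param path Output path.
#' @param frames Indices of frames to write; defaults to all.
#' @return `path`, invisibly.
#' @export
write_frames <- function(x, path, frames = NULL) {
  stopifnot(inherits(x, "frame_set"))
  if (is.null(frames)) frames <- seq_along(x$frames)
  at <- x$atoms
  blocks <- character(0)
  multi <- length(frames) > 1
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  for (k in seq_along(frames)) {
    f <- x$frames[[frames[k]]]
    bio3d::write.pdb(file = tmp,
                     xyz = as.numeric(t(f)),
                     type = ifelse(at$is_ligand, "HETATM", "ATOM"),
                     resno = at$resno, resid = at$resname,
                     eleno = seq_len(nrow(at)), elety = at$name,
                     chain = at$chain, elesy = at$element,
                     o = rep(1, nrow(at)), b = rep(0, nrow(at)))
    lines <- readLines(tmp)
    lines <- lines[!grepl("^END\\s*$|^END$", lines)]
    if (multi) lines <- c(sprintf("MODEL     %4d", k), lines, "ENDMDL")
    blocks <- c(blocks, lines)
  }
  writeLines(c(blocks, "END"), path)
  invisible(path)
}

#' Binding-site specification
#'
#' @param atom_indices Integer indices (into the frame-set atom table) of the
#'   binding-site atoms.
#' @param cutoff Distance cutoff in Angstrom used for the selection.
#' @param reference_frame Frame index the selection was resolved on.
#' @return An object of class `binding_site_spec`.
#' @export
binding_site_spec <- function(atom_indices, cutoff = 5, reference_frame = 1L) {
  atom_indices <- as.integer(atom_indices)
  if (length(atom_indices) == 0) stop("binding site must contain >= 1 atom")
  if (cutoff <= 0) stop("cutoff must be positive")
  structure(list(cutoff = cutoff,
                 reference_frame = as.integer(reference_frame),
                 atom_indices = atom_indices),
            class = "binding_site_spec")
}

#' Select the binding site around the ligand
#'
#' Protein heavy atoms whose minimum distance to any ligand heavy atom is at
#' most `cutoff` (default 5.0 Angstrom) in the reference frame. The selection
#' is frozen from that frame so the RMSD atom set is identical across all
#' frames.
#'
#' @param frames A `frame_set` with a flagged ligand.
#' @param cutoff Distance cutoff in Angstrom.
#' @param reference_frame Frame index used to resolve the selection.
#' @return A [binding_site_spec()].
#' @export
select_binding_site <- function(frames, cutoff = 5, reference_frame = 1L) {
  stopifnot(inherits(frames, "frame_set"))
  if (cutoff <= 0) stop("cutoff must be positive")
  if (reference_frame < 1 || reference_frame > length(frames$frames))
    stop("invalid reference frame index")
  at <- frames$atoms
  co <- frames$frames[[reference_frame]]
  heavy <- at$element != "H"
  lig <- which(at$is_ligand & heavy)
  if (length(lig) == 0) stop("no ligand heavy atoms flagged")
  prot <- which(!at$is_ligand & heavy)
  if (length(prot) == 0) stop("no protein heavy atoms")
  d2min <- rep(Inf, length(prot))
  P <- co[prot, , drop = FALSE]
  for (l in lig) {
    dl <- (P[, 1] - co[l, 1])^2 + (P[, 2] - co[l, 2])^2 + (P[, 3] - co[l, 3])^2
    d2min <- pmin(d2min, dl)
  }
  sel <- prot[d2min <= cutoff^2]
  if (length(sel) == 0)
    stop("empty binding site: no protein heavy atom within ", cutoff,
         " Angstrom of the ligand")
  binding_site_spec(sel, cutoff = cutoff, reference_frame = reference_frame)
}

#' Heavy-atom RMSD between two coordinate frames
#'
#' Root-mean-square deviation over the selected atoms, optionally after an
#' optimal least-squares (Kabsch) rigid superposition on those same atoms.
#'
#' @param frame_a,frame_b Numeric n_atoms x 3 coordinate matrices.
#' @param atom_indices Atom indices the RMSD is computed over.
#' @param superpose If `TRUE`, superpose `frame_b` onto `frame_a` on the
#'   selected atoms first.
#' @return RMSD in Angstrom.
#' @export
rmsd_frames <- function(frame_a, frame_b, atom_indices, superpose = FALSE) {
  if (length(atom_indices) == 0) stop("empty atom index set")
  a <- as.matrix(frame_a)[atom_indices, , drop = FALSE]
  b <- as.matrix(frame_b)[atom_indices, , drop = FALSE]
  if (!identical(dim(a), dim(b))) stop("frames disagree on selected atoms")
  av <- as.numeric(t(a))
  bv <- as.numeric(t(b))
  as.numeric(bio3d::rmsd(av, bv, fit = superpose))
}

#' Pairwise RMSD matrix over the binding-site atoms
#'
#' @param frames A `frame_set`.
#' @param site A [binding_site_spec()].
#' @param superpose Superpose each pair on the site atoms before the RMSD
#'   (default `TRUE`, the convention for MD frames).
#' @return Symmetric n_frames x n_frames matrix with zero diagonal.
#' @export
pairwise_rmsd_matrix <- function(frames, site, superpose = TRUE) {
  stopifnot(inherits(frames, "frame_set"), inherits(site, "binding_site_spec"))
  n <- length(frames$frames)
  D <- matrix(0, n, n)
  idx <- site$atom_indices
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <-
        rmsd_frames(frames$frames[[i]], frames$frames[[j]], idx,
                    superpose = superpose)
    }
  }
  D
}

#' Affinity-propagation clustering of a distance matrix
#'
#' Standard message-passing (responsibility/availability) clustering on the
#' similarity `s(i, j) = -d(i, j)^2` with the self-similarity set to
#' `preference`. Deterministic for fixed inputs; the number of clusters is
#' not preset but emerges from the preference (larger preference, more
#' exemplars). After convergence the exemplar of each cluster is refined to
#' the member maximising the summed within-cluster similarity.
#'
#' @param distance_matrix Square symmetric non-negative matrix, zero diagonal.
#' @param preference Self-similarity; the default `"median"` uses the median
#'   off-diagonal similarity.
#' @param damping Message damping factor in `[0.5, 1)`.
#' @param max_iter Maximum number of message-passing iterations.
#' @param convergence_iter Stop once the exemplar set is stable this many
#'   consecutive iterations.
#' @return An object of class `cluster_assignment`: list with `exemplars`
#'   (frame indices, ascending), `labels` (per-point cluster index into
#'   `exemplars`), `populations`, `n_iter`, `preference`.
#' @export
affinity_propagation <- function(distance_matrix, preference = "median",
                                 damping = 0.9, max_iter = 1000,
                                 convergence_iter = 50) {
  D <- as.matrix(distance_matrix)
  n <- nrow(D)
  if (n != ncol(D)) stop("distance matrix must be square")
  if (any(abs(D - t(D)) > 1e-8)) stop("distance matrix must be symmetric")
  if (!(damping >= 0.5 && damping < 1)) stop("damping must be in [0.5, 1)")
  if (n == 1)
    return(structure(list(exemplars = 1L, labels = 1L, populations = 1L,
                          n_iter = 0L, preference = NA_real_),
                     class = "cluster_assignment"))
  S <- -(D^2)
  if (identical(preference, "median")) {
    off <- S[row(S) != col(S)]
    preference <- stats::median(off)
  }
  diag(S) <- preference
  R <- A <- matrix(0, n, n)
  ii <- seq_len(n)
  E_prev <- rep(FALSE, n)
  stable <- 0L
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # responsibilities
    AS <- A + S
    i1 <- max.col(AS, ties.method = "first")
    m1 <- AS[cbind(ii, i1)]
    AS[cbind(ii, i1)] <- -Inf
    m2 <- AS[cbind(ii, max.col(AS, ties.method = "first"))]
    Rnew <- S - m1
    Rnew[cbind(ii, i1)] <- S[cbind(ii, i1)] - m2
    R <- damping * R + (1 - damping) * Rnew
    # availabilities
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    cs <- colSums(Rp)
    Anew <- pmin(matrix(cs, n, n, byrow = TRUE) - Rp, 0)
    diag(Anew) <- cs - diag(R)
    A <- damping * A + (1 - damping) * Anew
    E <- (diag(A) + diag(R)) > 0
    if (identical(E, E_prev) && any(E)) stable <- stable + 1L else stable <- 0L
    E_prev <- E
    if (stable >= convergence_iter) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    cond <- structure(
      class = c("ensdock_ap_no_convergence", "error", "condition"),
      list(message = sprintf(
             "affinity propagation did not converge within %d iterations", max_iter),
           call = sys.call(-1),
           partial = list(R = R, A = A, exemplar_mask = E_prev, n_iter = it)))
    stop(cond)
  }
  I <- which(E_prev)
  K <- length(I)
  cl <- max.col(S[, I, drop = FALSE], ties.method = "first")
  cl[I] <- seq_len(K)
  for (k in seq_len(K)) {
    memb <- which(cl == k)
    j <- which.max(colSums(S[memb, memb, drop = FALSE]))
    I[k] <- memb[j]
  }
  cl <- max.col(S[, I, drop = FALSE], ties.method = "first")
  cl[I] <- seq_len(K)
  exemplar_of_point <- I[cl]
  exemplars <- sort(unique(exemplar_of_point))
  labels <- match(exemplar_of_point, exemplars)
  structure(
    list(exemplars = as.integer(exemplars), labels = as.integer(labels),
         populations = tabulate(labels, nbins = length(exemplars)),
         n_iter = it, preference = preference),
    class = "cluster_assignment"
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d cluster(s) over %d point(s); populations: %s\n",
              length(x$exemplars), length(x$labels),
              paste(x$populations, collapse = ", ")))
  invisible(x)
}

#' Representative frames from a clustering
#'
#' Exemplar frames of the `n` most populated clusters, in descending
#' population order (population ties broken by lower cluster index). If
#' fewer than `n` clusters exist, all exemplars are returned with a warning.
#'
#' @param assignment A `cluster_assignment`.
#' @param n Number of representatives requested (default 3).
#' @return Integer vector of frame indices.
#' @export
representatives <- function(assignment, n = 3) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  if (n < 1) stop("n must be >= 1")
  K <- length(assignment$exemplars)
  ord <- order(-assignment$populations, seq_len(K))
  if (K < n) {
    warning(sprintf("only %d cluster(s) available, returning all", K))
    n <- K
  }
  assignment$exemplars[ord[seq_len(n)]]
}

#' Cluster single-frame structures by binding-site similarity
#'
#' Maps the structures onto a common atom set (intersection of residue
#' number + atom name keys), resolves the binding site on the first
#' structure, computes pairwise superposed binding-site RMSDs, clusters them
#' by average-linkage hierarchical clustering cut at `n_clusters`, and
#' returns the per-cluster medoid (minimum summed intra-cluster distance;
#' ties and the all-identical degenerate case resolve to the earliest
#' structure).
#'
#' @param structures Named list of single-frame `frame_set` objects.
#' @param n_clusters Number of clusters to cut the tree at (default 5).
#' @param cutoff Binding-site distance cutoff in Angstrom.
#' @return Character vector of medoid structure names (or indices as
#'   character if the list is unnamed), one per cluster.
#' @export
cluster_structures_by_site <- function(structures, n_clusters = 5, cutoff = 5) {
  if (length(structures) == 0) stop("need >= 1 structure")
  lapply(structures, function(s) stopifnot(inherits(s, "frame_set")))
  if (n_clusters < 1 || n_clusters > length(structures))
    stop("n_clusters must be between 1 and the number of structures")
  nm <- names(structures)
  if (is.null(nm)) nm <- as.character(seq_along(structures))
  keys <- lapply(structures, function(s)
    paste(s$atoms$resno, s$atoms$name, sep = "\001"))
  common <- Reduce(intersect, keys)
  if (length(common) == 0) stop("no common binding-site atom set across structures")
  # reorder every structure onto the common key set
  coords <- lapply(seq_along(structures), function(i) {
    structures[[i]]$frames[[1]][match(common, keys[[i]]), , drop = FALSE]
  })
  ref <- structures[[1]]
  ref_idx <- match(common, keys[[1]])
  sub_atoms <- ref$atoms[ref_idx, , drop = FALSE]
  sub_atoms$atom_id <- seq_len(nrow(sub_atoms))
  ref_common <- frame_set(sub_atoms, list(ref$frames[[1]][ref_idx, , drop = FALSE]))
  site <- select_binding_site(ref_common, cutoff = cutoff)
  idx <- site$atom_indices
  n <- length(structures)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- rmsd_frames(coords[[i]], coords[[j]], idx,
                                        superpose = TRUE)
    }
  }
  cl <- if (n_clusters == n) seq_len(n) else
    stats::cutree(stats::hclust(stats::as.dist(D), method = "average"),
                  k = n_clusters)
  medoids <- vapply(sort(unique(cl)), function(k) {
    memb <- which(cl == k)
    memb[which.min(rowSums(D[memb, memb, drop = FALSE]))]
  }, integer(1))
  nm[medoids]
}

.VDW_RADII <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8, H = 1.2)
.VDW_DEFAULT <- 1.7

#' Grid-based pocket volume
#'
#' Estimates the enclosed cavity volume around the binding site: a regular
#' grid of cell-centred points spans the bounding box of the site atoms
#' (padded by the probe radius plus one grid spacing); a point is free if it
#' lies farther than `vdW + probe_radius` from every protein atom; free
#' points reachable from the box boundary by 6-connected flood fill are
#' solvent, the remaining free points are cavity. Volume = cavity points x
#' spacing^3.
#'
#' @param frames A `frame_set`.
#' @param site A [binding_site_spec()] defining the pocket region.
#' @param frame Frame index to measure (default 1).
#' @param grid_spacing Grid spacing in Angstrom (default 0.5).
#' @param probe_radius Solvent probe radius in Angstrom (default 1.4).
#' @param radii Named vector of van der Waals radii by element; unknown
#'   elements fall back to 1.7 Angstrom.
#' @return Cavity volume in cubic Angstrom.
#' @export
pocket_volume <- function(frames, site, frame = 1, grid_spacing = 0.5,
                          probe_radius = 1.4, radii = .VDW_RADII) {
  stopifnot(inherits(frames, "frame_set"), inherits(site, "binding_site_spec"))
  co <- frames$frames[[frame]]
  at <- frames$atoms
  prot <- which(!at$is_ligand)
  if (length(prot) == 0) stop("no protein atoms")
  P <- co[prot, , drop = FALSE]
  r <- unname(radii[at$element[prot]])
  r[is.na(r)] <- .VDW_DEFAULT
  thr2 <- (r + probe_radius)^2
  box <- co[site$atom_indices, , drop = FALSE]
  pad <- probe_radius + grid_spacing
  lo <- apply(box, 2, min) - pad
  hi <- apply(box, 2, max) + pad
  if (any(hi - lo < grid_spacing)) stop("degenerate bounding box")
  ax <- lapply(1:3, function(d) {
    seq(lo[d] + grid_spacing / 2, hi[d], by = grid_spacing)
  })
  nx <- length(ax[[1]]); ny <- length(ax[[2]]); nz <- length(ax[[3]])
  G <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                             KEEP.OUT.ATTRS = FALSE))
  npt <- nrow(G)
  free <- logical(npt)
  chunk <- 4000L
  Pt <- t(P)
  p2 <- colSums(Pt^2)
  for (s in seq(1L, npt, by = chunk)) {
    e <- min(s + chunk - 1L, npt)
    Gc <- G[s:e, , drop = FALSE]
    d2 <- outer(rowSums(Gc^2), p2, "+") - 2 * (Gc %*% Pt)
    occ <- d2 <= matrix(thr2, nrow(Gc), length(thr2), byrow = TRUE)
    free[s:e] <- !apply(occ, 1, any)
  }
  vol <- array(free, dim = c(nx, ny, nz))
  reach <- array(FALSE, dim = c(nx, ny, nz))
  reach[c(1, nx), , ] <- vol[c(1, nx), , ]
  reach[, c(1, ny), ] <- reach[, c(1, ny), ] | vol[, c(1, ny), ]
  reach[, , c(1, nz)] <- reach[, , c(1, nz)] | vol[, , c(1, nz)]
  repeat {
    grown <- reach
    grown[-1, , ] <- grown[-1, , ] | reach[-nx, , ]
    grown[-nx, , ] <- grown[-nx, , ] | reach[-1, , ]
    grown[, -1, ] <- grown[, -1, ] | reach[, -ny, ]
    grown[, -ny, ] <- grown[, -ny, ] | reach[, -1, ]
    grown[, , -1] <- grown[, , -1] | reach[, , -nz]
    grown[, , -nz] <- grown[, , -nz] | reach[, , -1]
    grown <- grown & vol
    if (identical(grown, reach)) break
    reach <- grown
  }
  sum(vol & !reach) * grid_spacing^3
}
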