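#' Configuration for the synthetic score-matrix generator
#'
#' Encodes the study conditions the generator emulates: class sizes matching
#' a curated nuclear-receptor screening benchmark (118 agonists, 115
#' antagonists, 3000 property-matched decoys, i.e. an actives:decoys ratio
#' near 1:30), a conformation pool of agonist-like and antagonist-like
#' receptor conformations, class-by-conformation-type Gaussian score
#' distributions, and Bernoulli per-cell docking failures. Defaults plant
#' the qualitative structure observed in real screens: agonists dock well
#' everywhere (promiscuous), antagonists dock well only on antagonist-like
#' conformations and often fail on agonist-like ones, decoys dock poorly
#' everywhere.
#'
#' @param n_agonists,n_antagonists,n_decoys Ligand counts per class.
#' @param n_agonist_like,n_antagonist_like Conformation pool composition
#'   (default 6 + 6 = 12, four trajectories x three representatives).
#' @param means,sds 3 x 2 numeric matrices (rows agonist/antagonist/decoy,
#'   columns agonist_like/antagonist_like) of score means and standard
#'   deviations in docking-score units (lower = better).
#' @param fail_probs 3 x 2 matrix of per-cell docking-failure probabilities.
#' @param seed Integer RNG seed; the generator is fully reproducible from it.
#' @return An object of class `score_gen_config`.
#' @export
score_gen_config <- function(n_agonists = 118, n_antagonists = 115,
                             n_decoys = 3000,
                             n_agonist_like = 6, n_antagonist_like = 6,
                             means = NULL, sds = NULL, fail_probs = NULL,
                             seed = 1) {
  dn <- list(c("agonist", "antagonist", "decoy"),
             c("agonist_like", "antagonist_like"))
  if (is.null(means))
    means <- matrix(c(-11, -11,   # agonists favourable everywhere
                      -6, -11,    # antagonists favourable on antagonist-like only
                      -4, -4),    # decoys unfavourable
                    nrow = 3, byrow = TRUE, dimnames = dn)
  if (is.null(sds))
    sds <- matrix(1, 3, 2, dimnames = dn)
  if (is.null(fail_probs)) {
    fail_probs <- matrix(0, 3, 2, dimnames = dn)
    # antagonists often cannot be docked into agonist-like conformations
    fail_probs["antagonist", "agonist_like"] <- 0.3
  }
  for (m in list(means, sds, fail_probs))
    if (!identical(dim(m), c(3L, 2L)))
      stop("means, sds and fail_probs must be 3 x 2 matrices")
  dimnames(means) <- dimnames(sds) <- dimnames(fail_probs) <- dn
  counts <- c(n_agonists, n_antagonists, n_decoys,
              n_agonist_like, n_antagonist_like)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (n_agonist_like + n_antagonist_like < 1)
    stop("need at least one conformation")
  if (n_agonists + n_antagonists + n_decoys < 1)
    stop("need at least one ligand")
  if (any(sds < 0)) stop("standard deviations must be >= 0")
  if (any(fail_probs < 0 | fail_probs > 1))
    stop("failure probabilities must be in [0, 1]")
  structure(
    list(n_agonists = n_agonists, n_antagonists = n_antagonists,
         n_decoys = n_decoys, n_agonist_like = n_agonist_like,
         n_antagonist_like = n_antagonist_like,
         means = means, sds = sds, fail_probs = fail_probs,
         seed = as.integer(seed)),
    class = "score_gen_config"
  )
}

#' Generate a synthetic docking score matrix with planted structure
#'
#' Each cell is drawn from the class x conformation-type Gaussian of the
#' config unless a Bernoulli docking failure fires for that cell. Fully
#' reproducible from `config$seed`.
#'
#' @param config A [score_gen_config()].
#' @return List with `matrix` (a [score_matrix()]), `labels`
#'   (a [ligand_labels()]), and `truth` (planted ground truth: per-ligand
#'   class, per-conformation type, and the config).
#' @export
gen_score_matrix <- function(config) {
  stopifnot(inherits(config, "score_gen_config"))
  set.seed(config$seed)
  lig_class <- rep(c("agonist", "antagonist", "decoy"),
                   c(config$n_agonists, config$n_antagonists, config$n_decoys))
  lig_ids <- c(
    sprintf("ago_%03d", seq_len(config$n_agonists)),
    sprintf("ant_%03d", seq_len(config$n_antagonists)),
    sprintf("dec_%04d", seq_len(config$n_decoys)))
  conf_type <- rep(c("agonist_like", "antagonist_like"),
                   c(config$n_agonist_like, config$n_antagonist_like))
  conf_ids <- c(
    sprintf("agolike_%02d", seq_len(config$n_agonist_like)),
    sprintf("antlike_%02d", seq_len(config$n_antagonist_like)))
  nl <- length(lig_ids)
  nc <- length(conf_ids)
  scores <- matrix(NA_real_, nl, nc, dimnames = list(lig_ids, conf_ids))
  failed <- matrix(FALSE, nl, nc, dimnames = list(lig_ids, conf_ids))
  for (j in seq_len(nc)) {
    ty <- conf_type[j]
    mu <- config$means[lig_class, ty]
    sd <- config$sds[lig_class, ty]
    pf <- config$fail_probs[lig_class, ty]
    scores[, j] <- stats::rnorm(nl, mean = mu, sd = sd)
    failed[, j] <- stats::runif(nl) < pf
  }
  scores[failed] <- NA_real_
  list(
    matrix = score_matrix(scores, failed),
    labels = ligand_labels(lig_ids, lig_class),
    truth = list(ligand_class = stats::setNames(lig_class, lig_ids),
                 conformation_type = stats::setNames(conf_type, conf_ids),
                 config = config)
  )
}

#' Generate a toy frame set with planted conformational clusters
#'
#' Builds a small synthetic protein-plus-ligand system: a ligand at the
#' origin, a shell of binding-site atoms around it, and a distal shell
#' outside the site cutoff. Frames fall into `n_clusters` planted
#' conformations: each cluster beyond the first displaces every binding-site
#' atom by `center_separation` Angstrom along a cluster-specific random
#' direction (a non-rigid deformation, so superposition cannot remove it),
#' and every atom of every frame gets isotropic Gaussian jitter of
#' `jitter_sd`. Reproducible from `seed`.
#'
#' @param n_clusters Number of planted conformational clusters.
#' @param frames_per_cluster Frames per cluster.
#' @param jitter_sd Per-coordinate Gaussian jitter in Angstrom.
#' @param center_separation Offset between adjacent cluster centres in
#'   Angstrom.
#' @param seed Integer RNG seed.
#' @return List with `frames` (a [frame_set()]) and `labels` (planted
#'   cluster index per frame).
#' @export
gen_toy_frames <- function(n_clusters = 3, frames_per_cluster = 10,
                           jitter_sd = 0.1, center_separation = 10, seed = 1) {
  if (n_clusters < 1 || frames_per_cluster < 1) stop("counts must be >= 1")
  if (center_separation <= 0) stop("center_separation must be positive")
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")
  set.seed(as.integer(seed))
  # ligand: 5 heavy atoms in a small cross at the origin
  lig_xyz <- rbind(c(0, 0, 0), c(1.4, 0, 0), c(-1.4, 0, 0),
                   c(0, 1.4, 0), c(0, -1.4, 0))
  # binding-site shell: 20 atoms at radius 4 (inside the 5 A cutoff)
  n_site <- 20
  gold <- pi * (3 - sqrt(5))
  k <- seq_len(n_site)
  z <- 1 - (2 * k - 1) / n_site
  rho <- sqrt(pmax(0, 1 - z^2))
  site_xyz <- 4 * cbind(rho * cos(gold * k), rho * sin(gold * k), z)
  # distal shell: 15 atoms at radius 15 (outside the cutoff)
  n_far <- 15
  k <- seq_len(n_far)
  z <- 1 - (2 * k - 1) / n_far
  rho <- sqrt(pmax(0, 1 - z^2))
  far_xyz <- 15 * cbind(rho * cos(gold * k), rho * sin(gold * k), z)
  base <- rbind(lig_xyz, site_xyz, far_xyz)
  n_atoms <- nrow(base)
  site_rows <- nrow(lig_xyz) + seq_len(n_site)
  atoms <- data.frame(
    atom_id = seq_len(n_atoms),
    name = c(paste0("C", seq_len(nrow(lig_xyz))),
             paste0("CA", seq_len(n_site)),
             paste0("CB", seq_len(n_far))),
    element = "C",
    resno = c(rep(900L, nrow(lig_xyz)), seq_len(n_site), 100L + seq_len(n_far)),
    resname = c(rep("LIG", nrow(lig_xyz)), rep("ALA", n_site + n_far)),
    chain = "A",
    is_ligand = c(rep(TRUE, nrow(lig_xyz)), rep(FALSE, n_site + n_far)),
    stringsAsFactors = FALSE)
  labels <- rep(seq_len(n_clusters), each = frames_per_cluster)
  # per-cluster deformation field: cluster 1 is the undisplaced reference;
  # each later cluster displaces every site atom by center_separation along
  # its own fixed random direction (drawn once, before the frame jitter)
  disp <- vector("list", n_clusters)
  disp[[1]] <- matrix(0, n_site, 3)
  if (n_clusters > 1) {
    for (cl in 2:n_clusters) {
      dirs <- matrix(stats::rnorm(n_site * 3), n_site, 3)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      disp[[cl]] <- center_separation * dirs
    }
  }
  frames <- lapply(labels, function(cl) {
    f <- base
    f[site_rows, ] <- f[site_rows, ] + disp[[cl]]
    f + matrix(stats::rnorm(n_atoms * 3, sd = jitter_sd), n_atoms, 3)
  })
  list(frames = frame_set(atoms, frames), labels = labels)
}
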