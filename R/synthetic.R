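# Synthetic protein families with planted conformational sub-clusters.
#
# The generator fabricates an idealised alpha-helical CA trace, applies a
# hinge rotation of a fixed segment with a cluster-specific angle (the
# planted conformational difference), adds per-structure Gaussian
# coordinate noise, and hides everything behind a random rigid motion per
# structure so that only superposition-free statistics can recover the
# clusters.

# Run `expr` under a temporary RNG state derived from `seed`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Uniformly random rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Rodrigues rotation matrix for unit axis u and angle (radians).
rotation_about_axis <- function(u, angle) {
  u <- u / sqrt(sum(u^2))
  Kx <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * Kx + (1 - cos(angle)) * (Kx %*% Kx)
}

#' Idealised alpha-helix backbone trace
#'
#' Residue `i` (0-based) sits at \eqn{(r \cos i\theta, r \sin i\theta, ih)}
#' with radius r = 2.3 Angstroms, twist theta = 100 degrees and rise
#' h = 1.5 Angstroms per residue — the canonical alpha-helix parameters,
#' giving a consecutive-CA spacing of about 3.8 Angstroms. The trace is
#' fully determined by these parameters; `seed` is accepted for interface
#' uniformity with the other generators but does not influence the
#' coordinates.
#'
#' @param n_residues Number of residues (at least 4).
#' @param seed Unused; kept for a uniform generator interface.
#' @return An `n_residues` x 3 coordinate matrix (Angstroms).
#' @export
generate_backbone <- function(n_residues, seed = 0L) {
  if (n_residues < 4L)
    trmsd_error("size", "a backbone needs at least 4 residues")
  i <- seq_len(n_residues) - 1
  theta <- 100 * pi / 180
  cbind(2.3 * cos(i * theta), 2.3 * sin(i * theta), i * 1.5)
}

#' Hinge rotation of a backbone segment
#'
#' Rigidly rotates the residues of `segment` about a random axis (drawn
#' from `axis_seed`) through the segment's first residue, leaving all other
#' residues fixed. Distances within the segment and within its complement
#' are preserved; only cross distances change — the geometry of a hinge
#' (domain) motion.
#'
#' @param coords n x 3 coordinate matrix.
#' @param segment Integer vector of residue indices to rotate (contiguity
#'   is conventional but not required).
#' @param angle Rotation angle in degrees, in \[0, 180\] (0 is the
#'   identity).
#' @param axis_seed Seed fixing the hinge axis, so different angles share
#'   one axis. Ignored when `axis` is given.
#' @param axis Optional explicit 3-vector axis direction (need not be
#'   normalised); when `NULL` a random axis is drawn from `axis_seed`.
#' @return The perturbed coordinate matrix.
#' @export
hinge_perturbation <- function(coords, segment, angle, axis_seed = 1L,
                               axis = NULL) {
  if (length(segment) == 0L)
    trmsd_error("size", "hinge segment is empty")
  if (any(segment < 1L) || any(segment > nrow(coords)))
    trmsd_error("size", "hinge segment out of range")
  if (angle < 0 || angle > 180)
    trmsd_error("range", "hinge angle must lie in [0, 180] degrees")
  if (angle == 0) return(coords)
  if (is.null(axis)) axis <- with_seed(axis_seed, stats::rnorm(3))
  R <- rotation_about_axis(axis, angle * pi / 180)
  pivot <- coords[segment[1], ]
  out <- coords
  out[segment, ] <- sweep(sweep(coords[segment, , drop = FALSE], 2, pivot) %*% t(R),
                          2, pivot, `+`)
  out
}

#' Generate a synthetic protein family with planted conformational clusters
#'
#' Fabricates `n_clusters * per_cluster` structures of one helical fold.
#' Cluster `k` (k = 0, 1, ...) carries a hinge rotation of a fixed segment
#' (by default the C-terminal two thirds of the chain, hinged at the end
#' of the N-terminal third — a two-domain architecture with the large
#' domain reorienting) by `k * angle_step` degrees. The hinge axes are
#' cluster-specific and chosen so the planted conformations sit in general
#' position: the axis for cluster `k` is inclined from the helix axis by
#' the angle that keeps the effective bend of the moving domain at
#' `angle_step` for every cluster (the remainder of the rotation becomes
#' axial twist), with bend directions spread 60 degrees apart in azimuth.
#' Were all clusters bent about one shared axis — or bent by growing
#' angles in one direction — the intermediate clusters would be metrically
#' between their neighbours, a degenerate planting that no distance-based
#' clustering could recover as separate clans. Every structure then
#' receives independent Gaussian coordinate noise (sd `noise_sigma`,
#' applied after the perturbation so cluster separation is controlled by
#' `angle_step` alone) and a random rigid motion. The accompanying MSA is
#' the gapless identity alignment of one random amino-acid sequence;
#' optional `gap_columns` plant columns where the structures of every
#' second cluster lack the residue (the row shows `-`), exercising the
#' ungapped-column rule downstream.
#'
#' @param n_clusters Number of planted clusters (>= 2).
#' @param per_cluster Structures per cluster (>= 2).
#' @param n_residues Residues per structure.
#' @param noise_sigma Per-coordinate Gaussian noise sd, Angstroms.
#' @param angle_step Hinge angle increment between consecutive clusters,
#'   degrees.
#' @param seed Integer seed; the whole family is a deterministic function
#'   of the arguments.
#' @param segment Residue indices of the hinge segment; default is the
#'   C-terminal two thirds of the chain.
#' @param gap_columns Residue positions to plant as gap columns.
#' @return An object of class `trmsd_family`: list with `msa`
#'   (`trmsd_msa`), `structures` (named list of `trmsd_structure`),
#'   `truth` (named cluster labels), `perturbed_segment`, and `params`.
#' @examples
#' fam <- make_family(n_clusters = 2, per_cluster = 2, n_residues = 12,
#'                    noise_sigma = 0, angle_step = 30, seed = 1)
#' names(fam$structures)
#' @export
make_family <- function(n_clusters = 3L, per_cluster = 4L, n_residues = 40L,
                        noise_sigma = 0.1, angle_step = 30, seed = 1L,
                        segment = NULL, gap_columns = integer(0)) {
  if (n_clusters < 2L || per_cluster < 2L)
    trmsd_error("size", "need at least 2 clusters of at least 2 structures")
  if (noise_sigma < 0) trmsd_error("range", "noise_sigma must be >= 0")
  if ((n_clusters - 1L) * angle_step > 180)
    trmsd_error("range", "(n_clusters - 1) * angle_step must not exceed 180 degrees")
  if (is.null(segment))
    segment <- (n_residues %/% 3L):n_residues
  backbone <- generate_backbone(n_residues)
  with_seed(seed, {
    aa_seq <- sample(AA3TO1[1:20], n_residues, replace = TRUE)
    phi0 <- stats::runif(1, 0, 2 * pi)
    # Equal-bend axes: cluster k's rotation of k*angle_step is applied
    # about an axis inclined so the bend of the moving domain stays at
    # angle_step (excess rotation becomes twist), bend azimuths 60 deg
    # apart. This puts the planted conformations in general position;
    # a shared axis (or monotonically growing bends in one direction)
    # would leave intermediate clusters metrically between their
    # neighbours and unrecoverable as clans. Cluster 1 is unperturbed.
    step_rad <- angle_step * pi / 180
    refs <- lapply(seq_len(n_clusters) - 1L, function(k) {
      if (k == 0L || angle_step == 0) return(backbone)
      eta <- asin(min(1, sin(step_rad / 2) / sin(min(k * step_rad / 2, pi / 2))))
      phi <- phi0 + (k - 1) * pi / 3
      ax <- c(sin(eta) * cos(phi), sin(eta) * sin(phi), cos(eta))
      hinge_perturbation(backbone, segment, k * angle_step, axis = ax)
    })
    structures <- list()
    truth <- character(0)
    rows <- character(0)
    ids <- character(0)
    for (k in seq_len(n_clusters)) {
      for (j in seq_len(per_cluster)) {
        id <- sprintf("c%d_s%d", k, j)
        xyz <- refs[[k]]
        if (noise_sigma > 0)
          xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = noise_sigma), ncol = 3)
        xyz <- xyz %*% t(random_rotation())
        xyz <- sweep(xyz, 2, stats::runif(3, -20, 20), `+`)
        keep <- seq_len(n_residues)
        row <- aa_seq
        if (length(gap_columns) > 0L && k %% 2L == 0L) {
          keep <- setdiff(keep, gap_columns)
          row[gap_columns] <- "-"
        }
        residues <- data.frame(label = as.character(keep), aa = aa_seq[keep],
                               x = xyz[keep, 1], y = xyz[keep, 2], z = xyz[keep, 3],
                               stringsAsFactors = FALSE)
        structures[[id]] <- structure(
          list(seq_id = id, chain_id = "A", residues = residues),
          class = "trmsd_structure")
        truth[id] <- sprintf("cluster%d", k)
        rows <- c(rows, paste(row, collapse = ""))
        ids <- c(ids, id)
      }
    }
    msa <- new_msa(ids, rows)
    # the pivot residue lies on every hinge axis and does not move;
    # perturbed_segment records the columns that actually moved
    structure(list(
      msa = msa, structures = structures, truth = truth,
      perturbed_segment = setdiff(segment, segment[1]),
      params = list(n_clusters = n_clusters, per_cluster = per_cluster,
                    n_residues = n_residues, noise_sigma = noise_sigma,
                    angle_step = angle_step, seed = seed,
                    gap_columns = gap_columns)),
      class = "trmsd_family")
  })
}

#' @export
print.trmsd_family <- function(x, ...) {
  cat(sprintf(
    "Synthetic family: %d structures (%d clusters x %d), %d residues, hinge segment %d-%d\n",
    length(x$structures), x$params$n_clusters, x$params$per_cluster,
    x$params$n_residues, min(x$perturbed_segment), max(x$perturbed_segment)))
  invisible(x)
}

#' Write a synthetic family to disk
#'
#' Emits `msa.fasta`, one PDB file per structure, `templates.tsv` and
#' `truth_labels.tsv` under `dir` — a complete, self-contained input set
#' for [trmsd()] or the command-line `run` subcommand.
#'
#' @param family A `trmsd_family`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_family <- function(family, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_msa(family$msa, file.path(dir, "msa.fasta"), format = "fasta")
  tpl <- vapply(names(family$structures), function(id) {
    pdb <- paste0(id, ".pdb")
    write_structure_pdb(family$structures[[id]], file.path(dir, pdb))
    paste(id, pdb, "A", sep = "\t")
  }, character(1))
  writeLines(tpl, file.path(dir, "templates.tsv"))
  writeLines(c("seq_id\tcluster", paste(names(family$truth), family$truth, sep = "\t")),
             file.path(dir, "truth_labels.tsv"))
  invisible(dir)
}
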