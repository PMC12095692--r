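#' Residue contact fingerprint of one frame
#'
#' Residues having at least one heavy-atom pair at distance strictly below
#' `cutoff` Angstrom from any ligand heavy atom. Hydrogens on either side
#' are excluded (heavy atom - heavy atom criterion).
#'
#' @param traj An `lf_trajectory`.
#' @param frame Frame index (1-based).
#' @param cutoff Contact distance in Angstrom (default 4.0, strict `<`).
#' @return Character vector of contacted residues as `"chain:resid"`.
#' @export
contact_fingerprint <- function(traj, frame, cutoff = 4.0) {
  contact_fingerprints(traj, frames = frame, cutoff = cutoff)[[1]]
}

#' Residue contact fingerprints of many frames
#'
#' @param traj An `lf_trajectory`.
#' @param frames Frame indices (default all).
#' @param cutoff Contact distance in Angstrom (strict `<`).
#' @return Named list (by frame index) of `"chain:resid"` character vectors.
#' @export
contact_fingerprints <- function(traj, frames = seq_len(n_frames(traj)),
                                 cutoff = 4.0) {
  a <- traj$atoms
  lig <- which(a$is_ligand & a$element != "H")
  prot <- which(!a$is_ligand & a$element != "H")
  if (length(lig) == 0 || length(prot) == 0)
    abort("frame needs both ligand and protein heavy atoms")
  res_key <- paste0(a$chain[prot], ":", a$resid[prot])
  out <- lapply(frames, function(f) {
    xyz <- frame_coords(traj, f)
    L <- xyz[lig, , drop = FALSE]
    P <- xyz[prot, , drop = FALSE]
    d2 <- outer(rowSums(P^2), rowSums(L^2), "+") - 2 * P %*% t(L)
    hit <- apply(d2 < cutoff^2, 1, any)
    sort(unique(res_key[hit]))
  })
  stats::setNames(out, as.character(frames))
}

#' Select bound frames by contact richness
#'
#' A frame counts as bound when its fingerprint contains at least
#' `min_residues` distinct protein residues (default 5).
#'
#' @param traj An `lf_trajectory`.
#' @param fps Optional precomputed fingerprints
#'   ([contact_fingerprints()] output); computed if missing.
#' @param min_residues Minimum distinct contacted residues.
#' @param cutoff Contact cutoff (Angstrom) when computing fingerprints.
#' @return Integer vector of bound frame indices.
#' @export
filter_bound_frames <- function(traj, fps = NULL, min_residues = 5,
                                cutoff = 4.0) {
  fps <- fps %||% contact_fingerprints(traj, cutoff = cutoff)
  idx <- as.integer(names(fps))
  idx[lengths(fps) >= min_residues]
}

#' Ligand heavy-atom density grid over bound frames
#'
#' Superposes each bound frame's protein C-alpha atoms onto a reference
#' conformer (quaternion least squares), applies the fitted transform to the
#' ligand heavy atoms, and accumulates voxel counts. Optional symmetry
#' operators (rigid transforms) fold symmetry-equivalent positions onto one
#' asymmetric unit: every ligand position is replaced by the
#' lexicographically smallest of its images, so total counts are conserved.
#'
#' @param traj An `lf_trajectory`.
#' @param bound_frames Frame indices to accumulate.
#' @param spacing Voxel edge in Angstrom (default 1.0).
#' @param reference Reference protein coordinates (n_protein_heavy x 3
#'   matrix in trajectory atom order); default = first bound frame.
#' @param symmetry_ops List of `lf_transform` symmetry operators (identity
#'   implied).
#' @return An `lf_density_grid`: tibble of occupied voxels (`ix`, `iy`,
#'   `iz`, `count`, voxel-center `x`, `y`, `z`) with attributes `origin`,
#'   `spacing`, `dims`, `total`.
#' @export
density_grid <- function(traj, bound_frames, spacing = 1.0,
                         reference = NULL, symmetry_ops = list()) {
  a <- traj$atoms
  lig <- which(a$is_ligand & a$element != "H")
  ca <- which(!a$is_ligand & a$name == "CA")
  if (length(ca) < 3)
    abort("need >= 3 protein CA atoms for superposition")
  if (length(bound_frames) == 0)
    abort("no bound frames to accumulate")
  ref <- reference %||% frame_coords(traj, bound_frames[1])[ca, ,
                                                            drop = FALSE]
  pts <- list()
  for (f in bound_frames) {
    xyz <- frame_coords(traj, f)
    tf <- superpose_transform(xyz[ca, , drop = FALSE], ref)
    pts[[length(pts) + 1]] <- apply_transform(xyz[lig, , drop = FALSE], tf)
  }
  P <- do.call(rbind, pts)
  # symmetry folding: canonical image = lexicographically smallest
  if (length(symmetry_ops) > 0) {
    images <- c(list(P), lapply(symmetry_ops, function(op)
      apply_transform(P, op)))
    P <- t(vapply(seq_len(nrow(P)), function(i) {
      cand <- t(vapply(images, function(im) im[i, ], numeric(3)))
      cand[order(cand[, 1], cand[, 2], cand[, 3])[1], ]
    }, numeric(3)))
  }
  origin <- floor(apply(P, 2, min) / spacing) * spacing
  iv <- floor(sweep(P, 2, origin) / spacing)
  key <- paste(iv[, 1], iv[, 2], iv[, 3])
  tab <- table(key)
  ijk <- do.call(rbind, strsplit(names(tab), " "))
  grid <- tibble(
    ix = as.integer(ijk[, 1]), iy = as.integer(ijk[, 2]),
    iz = as.integer(ijk[, 3]), count = as.integer(tab)) |>
    dplyr::arrange(.data$ix, .data$iy, .data$iz) |>
    dplyr::mutate(x = origin[1] + (.data$ix + 0.5) * spacing,
                  y = origin[2] + (.data$iy + 0.5) * spacing,
                  z = origin[3] + (.data$iz + 0.5) * spacing)
  attr(grid, "origin") <- origin
  attr(grid, "spacing") <- spacing
  attr(grid, "dims") <- c(max(grid$ix), max(grid$iy), max(grid$iz)) + 1L
  attr(grid, "total") <- sum(grid$count)
  class(grid) <- c("lf_density_grid", class(grid))
  grid
}

#' Write a density grid in OpenDX format
#'
#' @param grid An `lf_density_grid` from [density_grid()].
#' @param path Output `.dx` path.
#' @return `path`, invisibly.
#' @export
write_dx <- function(grid, path) {
  origin <- attr(grid, "origin")
  spacing <- attr(grid, "spacing")
  dims <- attr(grid, "dims")
  arr <- array(0, dims)
  arr[cbind(grid$ix + 1L, grid$iy + 1L, grid$iz + 1L)] <- grid$count
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d",
            dims[1], dims[2], dims[3]),
    sprintf("origin %g %g %g", origin[1], origin[2], origin[3]),
    sprintf("delta %g 0 0", spacing),
    sprintf("delta 0 %g 0", spacing),
    sprintf("delta 0 0 %g", spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            dims[1], dims[2], dims[3]),
    sprintf(
      "object 3 class array type double rank 0 items %d data follows",
      prod(dims))), con)
  # OpenDX order: z varies fastest, x slowest
  vals <- as.vector(aperm(arr, c(3, 2, 1)))
  chunks <- split(vals, ceiling(seq_along(vals) / 3))
  writeLines(vapply(chunks, function(v)
    paste(format(v, trim = TRUE), collapse = " "), character(1)), con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}

#' Cluster contact fingerprints into epitopes
#'
#' Agglomerative clustering of binary residue-contact vectors: Jaccard
#' distance (`stats::dist(method = "binary")`), average linkage, cut at a
#' distance threshold. When a chain map is given, symmetry-equivalent
#' chains are first canonicalized onto one protomer so that symmetric
#' copies of an epitope cluster together. Deterministic.
#'
#' @param fps Named list of fingerprints ([contact_fingerprints()] output),
#'   typically restricted to bound frames.
#' @param linkage Agglomeration method (default "average").
#' @param cut Distance threshold at which the tree is cut (default 0.7).
#' @param chain_map Named character vector mapping chain -> canonical chain
#'   (e.g. `c(C = "A", D = "B")` for a 2-fold symmetric tetramer).
#' @return Tibble with columns `frame` (integer) and `cluster` (integer).
#' @export
cluster_fingerprints <- function(fps, linkage = "average", cut = 0.7,
                                 chain_map = NULL) {
  if (length(fps) < 1) abort("no fingerprints to cluster")
  frames <- as.integer(names(fps))
  canon <- lapply(fps, canonicalize_fp, chain_map = chain_map)
  univ <- sort(unique(unlist(canon)))
  M <- t(vapply(canon, function(fp) as.integer(univ %in% fp),
                integer(length(univ))))
  if (length(fps) == 1 || nrow(unique(M)) == 1) {
    return(tibble(frame = frames, cluster = 1L))
  }
  d <- stats::dist(M, method = "binary")
  hc <- stats::hclust(d, method = linkage)
  cl <- stats::cutree(hc, h = cut)
  # relabel clusters in order of first appearance for determinism
  cl <- as.integer(factor(cl, levels = unique(cl)))
  tibble(frame = frames, cluster = cl)
}

canonicalize_fp <- function(fp, chain_map = NULL) {
  if (is.null(chain_map) || length(fp) == 0) return(fp)
  parts <- strsplit(fp, ":", fixed = TRUE)
  mapped <- vapply(parts, function(p) {
    ch <- p[1]
    if (ch %in% names(chain_map)) ch <- chain_map[[ch]]
    paste0(ch, ":", p[2])
  }, character(1))
  sort(unique(mapped))
}

#' Epitope occupancy report
#'
#' Summarizes fingerprint clusters into occupancy-ranked epitopes. The
#' occupancy denominator is the total number of trajectory frames (site
#' population as a fraction of simulation time), switchable to bound frames
#' only. Per-residue contact frequencies are reported per cluster, with
#' user-designated hot-spot residues flagged.
#'
#' @param traj An `lf_trajectory`.
#' @param clusters Tibble from [cluster_fingerprints()].
#' @param fps Fingerprints for the clustered frames.
#' @param hot_spots Character vector of `"chain:resid"` (or bare resid)
#'   hot-spot residues to flag.
#' @param denominator `"all"` (default) or `"bound"`.
#' @return An `lf_epitope_report` tibble: one row per cluster with
#'   `epitope` (rank), `cluster`, `n_frames`, `occupancy_pct`, `frames`
#'   (list), `residues` (list of per-residue frequency tibbles).
#' @export
epitope_report <- function(traj, clusters, fps, hot_spots = character(),
                           denominator = c("all", "bound")) {
  denominator <- match.arg(denominator)
  total <- if (denominator == "all") n_frames(traj) else nrow(clusters)
  if (nrow(clusters) == 0) {
    out <- tibble(epitope = integer(), cluster = integer(),
                  n_frames = integer(), occupancy_pct = numeric(),
                  frames = list(), residues = list())
    attr(out, "total_frames") <- total
    class(out) <- c("lf_epitope_report", class(out))
    return(out)
  }
  hs <- as.character(hot_spots)
  rows <- clusters |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(n_frames = dplyr::n(),
                     frames = list(.data$frame), .groups = "drop") |>
    dplyr::mutate(occupancy_pct = 100 * .data$n_frames / total) |>
    dplyr::arrange(dplyr::desc(.data$occupancy_pct), .data$cluster) |>
    dplyr::mutate(epitope = dplyr::row_number())
  rows$residues <- lapply(rows$frames, function(fr) {
    sub <- fps[as.character(fr)]
    tab <- table(unlist(sub))
    tibble(residue = names(tab),
           frequency = as.numeric(tab) / length(sub)) |>
      dplyr::mutate(hot_spot = .data$residue %in% hs |
                      sub("^.*:", "", .data$residue) %in% hs) |>
      dplyr::arrange(dplyr::desc(.data$frequency), .data$residue)
  })
  out <- dplyr::select(rows, "epitope", "cluster", "n_frames",
                       "occupancy_pct", "frames", "residues")
  attr(out, "total_frames") <- total
  class(out) <- c("lf_epitope_report", class(out))
  out
}

#' Run the full epitope-detection pipeline on a trajectory
#'
#' Convenience wrapper: fingerprints -> bound-frame filter -> clustering ->
#' occupancy report.
#'
#' @param traj An `lf_trajectory`.
#' @param cutoff Contact cutoff in Angstrom.
#' @param min_residues Bound-frame threshold.
#' @param linkage,cut,chain_map Passed to [cluster_fingerprints()].
#' @param hot_spots,denominator Passed to [epitope_report()].
#' @return An `lf_epitope_report`.
#' @export
detect_epitopes <- function(traj, cutoff = 4.0, min_residues = 5,
                            linkage = "average", cut = 0.7,
                            chain_map = NULL, hot_spots = character(),
                            denominator = "all") {
  fps <- contact_fingerprints(traj, cutoff = cutoff)
  bound <- filter_bound_frames(traj, fps = fps,
                               min_residues = min_residues)
  if (length(bound) == 0) {
    return(epitope_report(traj, tibble(frame = integer(),
                                       cluster = integer()),
                          fps, hot_spots, denominator))
  }
  cl <- cluster_fingerprints(fps[as.character(bound)], linkage = linkage,
                             cut = cut, chain_map = chain_map)
  epitope_report(traj, cl, fps, hot_spots, denominator)
}
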