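# Independent oracles used to freeze expected values.

# Numeric 3D grid integration of the product of two summed-Gaussian
# densities (first-order model): independent check of the analytic pairwise
# overlap formula.
grid_overlap_oracle <- function(xyzA, xyzB, radius = 1.70, p = 2.7,
                                spacing = 0.05, pad = 5) {
  alpha <- pi * (3 * p / (4 * pi * radius^3))^(2 / 3)
  all_xyz <- rbind(xyzA, xyzB)
  lo <- apply(all_xyz, 2, min) - pad
  hi <- apply(all_xyz, 2, max) + pad
  gx <- seq(lo[1], hi[1], by = spacing)
  gy <- seq(lo[2], hi[2], by = spacing)
  gz <- seq(lo[3], hi[3], by = spacing)
  total <- 0
  # slab over z to keep memory modest
  for (z in gz) {
    pts_xy <- cbind(rep(gx, times = length(gy)),
                    rep(gy, each = length(gx)))
    dens <- function(xyz) {
      d <- matrix(0, nrow(pts_xy), 1)
      acc <- 0
      for (i in seq_len(nrow(xyz))) {
        d2 <- (pts_xy[, 1] - xyz[i, 1])^2 + (pts_xy[, 2] - xyz[i, 2])^2 +
          (z - xyz[i, 3])^2
        acc <- acc + p * exp(-alpha * d2)
      }
      acc
    }
    total <- total + sum(dens(xyzA) * dens(xyzB))
  }
  total * spacing^3
}

# Exhaustive pose-grid search over rotations x translations with its own
# Gaussian-overlap implementation (shared 1.70 A atom radius, amplitude
# 2.7, same-kind color terms). Coarse global grid, then a dense local grid
# around the coarse optimum at 10 degree / 0.1 Angstrom resolution.
pose_grid_oracle <- function(query, ref, rot_coarse = 30,
                             trans_coarse = 0.5, trans_span = 2) {
  p <- 2.7
  alpha_r <- function(r) pi * (3 * p / (4 * pi * r^3))^(2 / 3)
  aA <- alpha_r(1.70)
  featsQ <- assign_features(query)
  featsR <- assign_features(ref)
  A <- atom_coords(ref); B <- atom_coords(query)
  qc <- colMeans(B); rc <- colMeans(A)
  self_v <- function(X, alpha) {
    d2 <- as.matrix(stats::dist(X))^2
    sum(p^2 * (pi / (2 * alpha))^1.5 * exp(-alpha / 2 * d2))
  }
  vaa <- self_v(A, aA)
  vbb <- self_v(B, aA)
  kinds <- intersect(featsQ$kind, featsR$kind)
  aF <- alpha_r(1.0)
  self_c <- function(fe) {
    tot <- 0
    for (k in unique(fe$kind)) {
      X <- as.matrix(fe[fe$kind == k, c("x", "y", "z")])
      tot <- tot + self_v(X, aF)
    }
    tot
  }
  caa <- self_c(featsR); cbb <- self_c(featsQ)
  FR <- as.matrix(featsR[, c("x", "y", "z")])
  FQ <- as.matrix(featsQ[, c("x", "y", "z")])
  # combo for one rotation over a matrix of translations (T x 3), where the
  # query is rotated about its centroid onto the ref centroid plus t
  combos_for_rotation <- function(R, tg) {
    base <- as.numeric(rc - R %*% qc)
    cross_v <- function(X, Y, alpha) {
      # sum_ij k exp(-alpha/2 |x_i - y_j - t|^2) for every t row
      k <- p^2 * (pi / (2 * alpha))^1.5
      D <- matrix(0, nrow(X) * nrow(Y), 3)
      idx <- 1
      for (i in seq_len(nrow(X))) {
        for (j in seq_len(nrow(Y))) {
          D[idx, ] <- X[i, ] - Y[j, ]
          idx <- idx + 1
        }
      }
      rr <- rowSums(D^2)
      tt <- rowSums(tg^2)
      d2 <- outer(rr, tt, "+") - 2 * D %*% t(tg)
      k * colSums(exp(-alpha / 2 * d2))
    }
    Bp <- sweep(B %*% t(R), 2, -base)
    vab <- cross_v(A, Bp, aA)
    st <- vab / (vaa + vbb - vab)
    cab <- 0
    if (length(kinds) > 0 && caa + cbb > 0) {
      FQp <- sweep(FQ %*% t(R), 2, -base)
      for (kd in kinds) {
        cab <- cab + cross_v(FR[featsR$kind == kd, , drop = FALSE],
                             FQp[featsQ$kind == kd, , drop = FALSE], aF)
      }
    }
    ct <- if (is.numeric(cab) && caa + cbb > 0)
      cab / pmax(caa + cbb - cab, 1e-12) else 0
    st + ct
  }
  euler_R <- function(a, b, c) {
    ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
    cc <- cos(c); sc <- sin(c)
    Rz1 <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, byrow = TRUE)
    Rz2 <- matrix(c(cc, -sc, 0, sc, cc, 0, 0, 0, 1), 3, byrow = TRUE)
    Rz1 %*% Ry %*% Rz2
  }
  search <- function(angles, tg) {
    best <- list(combo = -Inf)
    for (ab in seq_len(nrow(angles))) {
      R <- euler_R(angles[ab, 1], angles[ab, 2], angles[ab, 3])
      sc <- combos_for_rotation(R, tg)
      i <- which.max(sc)
      if (sc[i] > best$combo)
        best <- list(combo = sc[i], angle = angles[ab, ], t = tg[i, ])
    }
    best
  }
  deg <- pi / 180
  a_seq <- seq(0, 360 - rot_coarse, by = rot_coarse) * deg
  b_seq <- seq(0, 180, by = rot_coarse) * deg
  angles <- as.matrix(expand.grid(a_seq, b_seq, a_seq))
  t_seq <- seq(-trans_span, trans_span, by = trans_coarse)
  tg <- as.matrix(expand.grid(t_seq, t_seq, t_seq))
  coarse <- search(angles, tg)
  fine_a <- lapply(coarse$angle, function(a)
    a + seq(-rot_coarse, rot_coarse, by = 10) * deg)
  angles2 <- as.matrix(expand.grid(fine_a[[1]], fine_a[[2]], fine_a[[3]]))
  t2 <- lapply(coarse$t, function(t0)
    t0 + seq(-trans_coarse, trans_coarse, by = 0.1))
  tg2 <- as.matrix(expand.grid(t2[[1]], t2[[2]], t2[[3]]))
  fine <- search(angles2, tg2)
  max(coarse$combo, fine$combo)
}

# Independent SDF record counter (ChemmineR); cross-checks the package's
# V2000 reader, which is authoritative for formal charges.
sdf_count_oracle <- function(path) {
  suppressWarnings(length(ChemmineR::read.SDFset(path)@SDF))
}

# O(N^2) all-pairs contact oracle over one frame
brute_force_contacts <- function(traj, frame, cutoff = 4.0) {
  a <- traj$atoms
  xyz <- traj$coords[frame, , ]
  dim(xyz) <- c(nrow(a), 3)
  lig <- which(a$is_ligand & a$element != "H")
  prot <- which(!a$is_ligand & a$element != "H")
  hits <- character()
  for (i in prot) {
    for (j in lig) {
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (d < cutoff) {
        hits <- c(hits, paste0(a$chain[i], ":", a$resid[i]))
        break
      }
    }
  }
  sort(unique(hits))
}
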