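#' Optimize the rigid overlay of a query molecule onto a reference
#'
#' Maximizes the Tanimoto-Combo score (shape Tanimoto + pharmacophore color
#' Tanimoto, range 0-2) over rigid motions of the query. Starting poses are
#' the inertial-frame alignment of the query onto the reference plus its
#' axis flips (5 deterministic starts) and, beyond those, seeded uniform
#' random rotations; each start is refined by derivative-free (Nelder-Mead)
#' ascent on the combo score. Ties between starts are broken by shape
#' Tanimoto. Deterministic for a given `seed` and `n_starts`.
#'
#' @param query,ref `lf_molecule` objects with 3D coordinates.
#' @param n_starts Number of starting poses (>= 1); default 16.
#' @param seed Integer seed for the random starts.
#' @param rules Feature ruleset used if features are not supplied.
#' @param featsQ,featsR Optional precomputed feature tibbles.
#' @param radii Optional per-element vdW radii; default shared 1.70 A.
#' @return An `lf_overlay` list: `transform` (the rigid motion applied to
#'   the query), `shape_tanimoto`, `color_tanimoto`, `combo`.
#' @export
optimize_overlay <- function(query, ref, n_starts = 16, seed = 42,
                             rules = default_feature_rules(),
                             featsQ = NULL, featsR = NULL, radii = NULL) {
  if (n_starts < 1) abort("`n_starts` must be >= 1")
  featsQ <- featsQ %||% assign_features(query, rules)
  featsR <- featsR %||% assign_features(ref, rules)

  xyzQ <- atom_coords(query); xyzR <- atom_coords(ref)
  qc <- colMeans(xyzQ); rc <- colMeans(xyzR)
  starts <- overlay_starts(xyzQ, xyzR, n_starts, seed)

  score_pose <- make_pose_scorer(query, ref, featsQ, featsR, radii)
  # perturbations rotate about the reference centroid, where the posed
  # query sits after every start (centroid-matched starts)
  objective <- function(par, base_tf) {
    tf <- perturb_transform(base_tf, par, rc)
    -score_pose(tf)[["combo"]]
  }
  best <- NULL
  for (tf0 in starts) {
    opt <- stats::optim(rep(0, 6), objective, base_tf = tf0,
                        method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-10))
    tf <- perturb_transform(tf0, opt$par, rc)
    sc <- score_pose(tf)
    sc0 <- score_pose(tf0)
    if (sc[["combo"]] < sc0[["combo"]]) { # refinement must not lose ground
      tf <- tf0; sc <- sc0
    }
    if (is.null(best) || sc[["combo"]] > best$combo + 1e-12 ||
        (abs(sc[["combo"]] - best$combo) <= 1e-12 &&
         sc[["shape"]] > best$shape_tanimoto)) {
      best <- list(transform = tf,
                   shape_tanimoto = unname(sc[["shape"]]),
                   color_tanimoto = unname(sc[["color"]]),
                   combo = unname(sc[["combo"]]))
    }
  }
  structure(best, class = "lf_overlay")
}

#' @export
print.lf_overlay <- function(x, ...) {
  cat(sprintf(
    "<lf_overlay> combo %.4f (shape %.4f + color %.4f)\n",
    x$combo, x$shape_tanimoto, x$color_tanimoto))
  invisible(x)
}

# Precomputed scorer: self-overlap volumes and feature Gaussians are fixed
# (rigid motions preserve them), so each pose evaluation only computes the
# cross terms.
make_pose_scorer <- function(query, ref, featsQ, featsR, radii = NULL) {
  gq <- mol_gauss(query, radii)
  gr <- mol_gauss(ref, radii)
  vaa <- gauss_overlap_sum(gr$xyz, gr$xyz, gr$alpha, gr$alpha)
  vbb <- gauss_overlap_sum(gq$xyz, gq$xyz, gq$alpha, gq$alpha)
  fq <- feat_gauss(featsQ); fr <- feat_gauss(featsR)
  kinds <- union(fq$kind, fr$kind)
  caa <- cbb <- 0
  for (k in kinds) {
    ia <- fr$kind == k; ib <- fq$kind == k
    if (any(ia))
      caa <- caa + gauss_overlap_sum(fr$xyz[ia, , drop = FALSE],
                                     fr$xyz[ia, , drop = FALSE],
                                     fr$alpha[ia], fr$alpha[ia])
    if (any(ib))
      cbb <- cbb + gauss_overlap_sum(fq$xyz[ib, , drop = FALSE],
                                     fq$xyz[ib, , drop = FALSE],
                                     fq$alpha[ib], fq$alpha[ib])
  }
  shared <- intersect(fq$kind, fr$kind)
  no_color <- nrow(featsQ) == 0 || nrow(featsR) == 0
  function(tf) {
    xq <- apply_transform(gq$xyz, tf)
    vab <- gauss_overlap_sum(gr$xyz, xq, gr$alpha, gq$alpha)
    st <- vab / (vaa + vbb - vab)
    ct <- 0
    if (!no_color && caa + cbb > 0) {
      fxq <- apply_transform(fq$xyz, tf)
      cab <- 0
      for (k in shared) {
        ia <- fr$kind == k; ib <- fq$kind == k
        cab <- cab + gauss_overlap_sum(fr$xyz[ia, , drop = FALSE],
                                       fxq[ib, , drop = FALSE],
                                       fr$alpha[ia], fq$alpha[ib])
      }
      if (caa + cbb - cab > 0) ct <- cab / (caa + cbb - cab)
    }
    c(shape = st, color = ct, combo = st + ct)
  }
}

# rotation applied about the query centroid, then translation
perturb_transform <- function(base_tf, par, qc) {
  Rp <- rotation_from_vector(par[1:3])
  tf_p <- rigid_transform(Rp, as.numeric(qc - Rp %*% qc) + par[4:6])
  compose_transform(tf_p, base_tf)
}

overlay_starts <- function(xyzQ, xyzR, n_starts, seed) {
  qc <- colMeans(xyzQ); rc <- colMeans(xyzR)
  center_tf <- function(R) rigid_transform(R, rc - as.numeric(R %*% qc))
  starts <- list(center_tf(diag(3)))
  # inertial alignment: principal axes of the heavy-atom covariance
  Vq <- principal_axes(xyzQ)
  Vr <- principal_axes(xyzR)
  flips <- list(diag(c(1, 1, 1)), diag(c(1, -1, -1)),
                diag(c(-1, 1, -1)), diag(c(-1, -1, 1)))
  for (D in flips) {
    R <- Vr %*% D %*% t(Vq)
    if (det(R) < 0) R <- Vr %*% D %*% diag(c(1, 1, -1)) %*% t(Vq)
    starts[[length(starts) + 1]] <- center_tf(R)
  }
  extra <- n_starts - length(starts)
  if (extra > 0) {
    rots <- with_seed(seed, replicate(extra, random_rotation(),
                                      simplify = FALSE))
    for (R in rots) starts[[length(starts) + 1]] <- center_tf(R)
  }
  starts[seq_len(min(n_starts, length(starts)))]
}

principal_axes <- function(xyz) {
  C <- stats::cov(sweep(xyz, 2, colMeans(xyz)))
  if (!all(is.finite(C))) C <- diag(3)
  V <- eigen(C + diag(3) * 1e-12, symmetric = TRUE)$vectors
  if (det(V) < 0) V[, 3] <- -V[, 3]
  V
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Screen a molecule library against a template
#'
#' Scores every library molecule against the template with
#' [optimize_overlay()], ranks by Tanimoto-Combo (ties broken by shape
#' Tanimoto, then molecule name), and tallies a census of molecules whose
#' combo exceeds each threshold. Molecules that fail feature assignment are
#' reported in the `skipped` attribute, not silently dropped.
#'
#' @param template `lf_molecule` used as the reference.
#' @param library List of `lf_molecule` to score.
#' @param thresholds Numeric thresholds for the census (combo > threshold).
#' @param n_starts,seed,rules,radii Passed to [optimize_overlay()].
#' @return An `lf_screen` tibble with columns `id`, `shape_tanimoto`,
#'   `color_tanimoto`, `combo`, `rank`; attributes `census` (named numeric)
#'   and `skipped` (character).
#' @export
screen_library <- function(template, library, thresholds = c(1.5, 1.4, 1.3),
                           n_starts = 16, seed = 42,
                           rules = default_feature_rules(), radii = NULL) {
  if (length(library) == 0) abort("`library` must be non-empty")
  featsR <- assign_features(template, rules)
  rows <- list()
  skipped <- character()
  for (i in seq_along(library)) {
    mol <- library[[i]]
    id <- mol$name %||% sprintf("mol_%d", i)
    featsQ <- tryCatch(assign_features(mol, rules), error = function(e) e)
    if (inherits(featsQ, "error")) {
      skipped <- c(skipped, sprintf("%s: %s", id,
                                    conditionMessage(featsQ)))
      next
    }
    ov <- optimize_overlay(mol, template, n_starts = n_starts,
                           seed = seed + i, rules = rules,
                           featsQ = featsQ, featsR = featsR, radii = radii)
    rows[[length(rows) + 1]] <- tibble(
      id = id, shape_tanimoto = ov$shape_tanimoto,
      color_tanimoto = ov$color_tanimoto, combo = ov$combo)
  }
  if (length(skipped) > 0)
    warn(paste0("skipped ", length(skipped), " molecule(s) failing ",
                "feature assignment; see attr(, 'skipped')"))
  res <- dplyr::bind_rows(rows) |>
    dplyr::arrange(dplyr::desc(.data$combo),
                   dplyr::desc(.data$shape_tanimoto), .data$id) |>
    dplyr::mutate(rank = dplyr::row_number())
  census <- vapply(thresholds, function(th) sum(res$combo > th), numeric(1))
  names(census) <- as.character(thresholds)
  attr(res, "census") <- census
  attr(res, "skipped") <- skipped
  class(res) <- c("lf_screen", class(res))
  res
}

#' Census of a screen report
#' @param report An `lf_screen` from [screen_library()].
#' @return Named numeric vector: threshold -> count of combo > threshold.
#' @export
screen_census <- function(report) attr(report, "census")

#' Check pharmacophore anchor points on an overlaid query
#'
#' Programmatic surrogate of visual pharmacophore inspection: for each
#' anchor (a template substructure centroid plus the required feature kind),
#' reports whether the overlaid query places a feature of the same kind
#' within `tolerance` Angstrom. An anchor whose kind is absent from the
#' query is reported unmatched, not an error.
#'
#' @param overlay `lf_overlay` from [optimize_overlay()].
#' @param query The query `lf_molecule` (or its feature tibble via
#'   `featsQ`).
#' @param anchors Tibble with columns `name`, `kind`, `x`, `y`, `z`.
#' @param tolerance Match distance in Angstrom (default 1.5).
#' @param rules Feature ruleset.
#' @param featsQ Optional precomputed query features.
#' @return Tibble with columns `name`, `kind`, `matched`, `distance`.
#' @export
pharmacophore_point_check <- function(overlay, query, anchors,
                                      tolerance = 1.5,
                                      rules = default_feature_rules(),
                                      featsQ = NULL) {
  featsQ <- featsQ %||% assign_features(query, rules)
  fx <- apply_transform(as.matrix(featsQ[, c("x", "y", "z")]),
                        overlay$transform)
  purrr::pmap_dfr(anchors, function(name, kind, x, y, z, ...) {
    sel <- featsQ$kind == kind
    if (!any(sel)) {
      return(tibble(name = name, kind = kind, matched = FALSE,
                    distance = NA_real_))
    }
    d <- sqrt(rowSums(sweep(fx[sel, , drop = FALSE], 2,
                            c(x, y, z))^2))
    tibble(name = name, kind = kind, matched = min(d) <= tolerance,
           distance = min(d))
  })
}
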