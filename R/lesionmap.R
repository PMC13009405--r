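#' Construct a binary lesion volume
#'
#' @param data 3D array; values are binarized at 0.5 on construction.
#' @param voxel_size_mm voxel edge lengths in mm (length 1 or 3).
#' @param space_tag template-space identifier carried through I/O.
#' @return object of class `lesion_volume`.
#' @export
lesion_volume <- function(data, voxel_size_mm = c(2, 2, 2),
                          space_tag = "synthetic-grid") {
  data <- array(as.integer(data > 0.5), dim = dim(data))
  if (length(dim(data)) != 3) stop_invalid("lesion data must be a 3D array")
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3)
  if (any(voxel_size_mm <= 0)) stop_invalid("voxel sizes must be positive")
  structure(list(data = data, voxel_size_mm = voxel_size_mm,
                 space_tag = space_tag),
            class = "lesion_volume")
}

lesion_cc <- function(vol) {
  sum(vol$data) * prod(vol$voxel_size_mm) / 1000
}

#' Bundle per-subject lesion volumes on one shared grid
#'
#' Verifies that all volumes share grid dimensions and voxel size, and that
#' any supplied `lesion_size_cc` agrees with the voxel count times voxel
#' volume (tolerance 1e-6 cc); sizes are recomputed when omitted.
#'
#' @param subjects character subject identifiers.
#' @param volumes list of [lesion_volume()] in the same order.
#' @param lesion_size_cc optional vector of sizes to verify against.
#' @return object of class `cohort_lesions`.
#' @export
cohort_lesions <- function(subjects, volumes, lesion_size_cc = NULL) {
  if (length(subjects) != length(volumes))
    stop_invalid("subjects and volumes must align")
  if (length(volumes)) {
    dims <- vapply(volumes, function(v) paste(dim(v$data), collapse = "x"),
                   character(1))
    if (length(unique(dims)) > 1) stop_invalid("all volumes must share one grid")
  }
  sizes <- vapply(volumes, lesion_cc, numeric(1))
  if (!is.null(lesion_size_cc) &&
      any(abs(sizes - lesion_size_cc) > 1e-6))
    stop_invalid("lesion_size_cc inconsistent with voxel counts")
  structure(list(subjects = as.character(subjects), volumes = volumes,
                 lesion_size_cc = sizes,
                 grid = if (length(volumes)) dim(volumes[[1]]$data) else NULL),
            class = "cohort_lesions")
}

#' @export
print.cohort_lesions <- function(x, ...) {
  cat(sprintf("Lesion cohort: %d subjects on %s grid, sizes %.1f-%.1f cc\n",
              length(x$subjects),
              paste(x$grid, collapse = "x"),
              if (length(x$subjects)) min(x$lesion_size_cc) else NA,
              if (length(x$subjects)) max(x$lesion_size_cc) else NA))
  invisible(x)
}

#' Construct a named tract atlas
#'
#' @param tracts named list of 1-based linear voxel indices (non-empty,
#'   unique names).
#' @param grid grid dimensions (3 integers).
#' @return object of class `tract_atlas`.
#' @export
tract_atlas <- function(tracts, grid) {
  if (!length(tracts) || is.null(names(tracts)) || anyDuplicated(names(tracts)))
    stop_invalid("tracts must be a non-empty uniquely named list")
  if (any(lengths(tracts) == 0)) stop_invalid("tract voxel sets must be non-empty")
  nvox <- prod(grid)
  tracts <- lapply(tracts, function(v) {
    v <- sort(unique(as.integer(v)))
    if (any(v < 1 | v > nvox)) stop_invalid("tract voxel index outside grid")
    v
  })
  structure(list(tracts = tracts, grid = as.integer(grid)),
            class = "tract_atlas")
}

#' Construct a streamline set
#'
#' @param streamlines list of 1-based linear voxel-index paths (non-empty).
#' @param grid grid dimensions.
#' @return object of class `streamline_set`.
#' @export
streamline_set <- function(streamlines, grid) {
  nvox <- prod(grid)
  streamlines <- lapply(streamlines, function(p) {
    p <- as.integer(p)
    if (!length(p)) stop_invalid("streamline paths must be non-empty")
    if (any(p < 1 | p > nvox)) stop_invalid("streamline voxel outside grid")
    p
  })
  structure(list(streamlines = streamlines, grid = as.integer(grid)),
            class = "streamline_set")
}

#' Voxel coverage filter
#'
#' Returns the voxels lesioned in at least `min_fraction` of the cohort,
#' with an inclusive comparison (`count / n >= min_fraction`): with 10
#' subjects a voxel lesioned in exactly one subject is retained at the
#' default 10% threshold, and with 63 subjects retention requires at least
#' 7.
#'
#' @param cohort a [cohort_lesions()] with >= 1 subject.
#' @param min_fraction minimum lesioned fraction, in (0, 1].
#' @return sorted integer vector of 1-based linear voxel indices.
#' @export
voxel_coverage_filter <- function(cohort, min_fraction = 0.10) {
  stopifnot(inherits(cohort, "cohort_lesions"))
  if (!is.numeric(min_fraction) || min_fraction <= 0 || min_fraction > 1)
    stop_invalid("min_fraction must lie in (0, 1]")
  n <- length(cohort$subjects)
  if (n < 1) stop_invalid("need at least one subject")
  counts <- Reduce(`+`, lapply(cohort$volumes, function(v) v$data))
  which(counts / n >= min_fraction)
}

#' Regress a covariate out of a behaviour vector
#'
#' OLS residuals of `behavior` on `covariate` with intercept; residuals are
#' mean-zero to numerical precision. Used to remove total lesion size from
#' symptom scores before lesion-symptom mapping.
#'
#' @param behavior,covariate aligned numeric vectors of length >= 3.
#' @return numeric residual vector.
#' @export
regress_out <- function(behavior, covariate) {
  if (length(behavior) != length(covariate) || length(behavior) < 3)
    stop_invalid("aligned vectors of length >= 3 required")
  if (stats::sd(behavior) == 0)
    stop_invalid("degenerate input: constant behavior")
  X <- cbind(1, covariate)
  if (stats::sd(covariate) == 0) X <- X[, 1, drop = FALSE]
  unname(qr.resid(qr(X), behavior))
}

#' Tract lesion percentages
#'
#' Per tract, `|lesion intersect tract| / |tract|` in `[0, 1]`.
#'
#' @param lesion a [lesion_volume()].
#' @param tract_atlas a [tract_atlas()] on the same grid.
#' @return named numeric vector of lesioned fractions per tract.
#' @export
tract_lesion_percentage <- function(lesion, tract_atlas) {
  stopifnot(inherits(lesion, "lesion_volume"), inherits(tract_atlas, "tract_atlas"))
  if (!identical(dim(lesion$data), tract_atlas$grid))
    stop_invalid("lesion and atlas are on different grids")
  les <- as.logical(lesion$data)
  vapply(tract_atlas$tracts, function(v) mean(les[v]), numeric(1))
}

#' Streamline disconnection map
#'
#' A template streamline is disconnected by a lesion when any voxel on its
#' path is lesioned. Per voxel the map reports the fraction of streamlines
#' traversing it that are disconnected (0 where no streamline passes); the
#' binary map thresholds the fraction inclusively (`>= binarize_threshold`,
#' default 50%).
#'
#' @param lesion a [lesion_volume()].
#' @param streamlines a [streamline_set()] on the same grid, >= 1 path.
#' @param binarize_threshold in (0, 1].
#' @return list with `fraction` and `binary` 3D arrays.
#' @export
disconnection_map <- function(lesion, streamlines, binarize_threshold = 0.5) {
  stopifnot(inherits(lesion, "lesion_volume"), inherits(streamlines, "streamline_set"))
  if (!identical(dim(lesion$data), streamlines$grid))
    stop_invalid("lesion and streamline grids differ")
  if (!length(streamlines$streamlines)) stop_invalid("need >= 1 streamline")
  if (binarize_threshold <= 0 || binarize_threshold > 1)
    stop_invalid("binarize_threshold must lie in (0, 1]")
  nvox <- prod(streamlines$grid)
  les <- as.logical(lesion$data)
  total <- integer(nvox); disc <- integer(nvox)
  for (path in streamlines$streamlines) {
    vox <- unique(path)
    total[vox] <- total[vox] + 1L
    if (any(les[vox])) disc[vox] <- disc[vox] + 1L
  }
  frac <- ifelse(total > 0, disc / pmax(total, 1L), 0)
  list(fraction = array(frac, dim = streamlines$grid),
       binary = array(as.integer(total > 0 & frac >= binarize_threshold),
                      dim = streamlines$grid))
}

#' Build a subjects-by-voxels binary matrix from cohort lesions
#'
#' @param cohort a [cohort_lesions()].
#' @param voxels linear voxel indices (typically from
#'   [voxel_coverage_filter()]); column names record the indices.
#' @return binary matrix, subjects x voxels.
#' @export
lesion_matrix <- function(cohort, voxels) {
  stopifnot(inherits(cohort, "cohort_lesions"))
  X <- t(vapply(cohort$volumes, function(v) as.numeric(v$data[voxels]),
                numeric(length(voxels))))
  rownames(X) <- cohort$subjects
  colnames(X) <- as.character(voxels)
  X
}

# hard-sparsity cap: keep the top `m` entries by magnitude
project_sparse <- function(w, m, signs_free) {
  if (!signs_free) w[w < 0] <- 0
  if (m < length(w) && sum(w != 0) > m) {
    cut <- sort(abs(w), decreasing = TRUE)[m]
    w[abs(w) < cut] <- 0
    # deterministic tie-break: keep lowest indices among ties at the cut
    at <- which(abs(w) == cut & w != 0)
    excess <- sum(w != 0) - m
    if (excess > 0) w[at[seq_len(excess) + (length(at) - excess)]] <- 0
  }
  w
}

# 6-neighbour mean smoother over the masked voxel set; identity when no
# grid information is available
make_mask_smoother <- function(vox, grid) {
  if (is.null(grid) || is.null(vox)) return(identity)
  vox <- as.integer(vox)
  co <- arrayInd(vox, grid)
  pos <- integer(prod(grid)); pos[vox] <- seq_along(vox)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  nb <- lapply(seq_len(6), function(o) {
    sh <- sweep(co, 2, offs[o, ], `+`)
    ok <- sh[, 1] >= 1 & sh[, 1] <= grid[1] & sh[, 2] >= 1 &
      sh[, 2] <= grid[2] & sh[, 3] >= 1 & sh[, 3] <= grid[3]
    out <- integer(length(vox))
    out[ok] <- pos[(sh[ok, 3] - 1L) * grid[1] * grid[2] +
                     (sh[ok, 2] - 1L) * grid[1] + sh[ok, 1]]
    out
  })
  function(w) {
    s <- w; cnt <- rep(1, length(w))
    for (o in seq_len(6)) {
      has <- nb[[o]] > 0L
      s[has] <- s[has] + w[nb[[o]][has]]
      cnt[has] <- cnt[has] + 1
    }
    s / cnt
  }
}

# 6-connected components of a displayed voxel set; drops small clusters
prune_clusters <- function(disp, grid, min_size) {
  if (!length(disp) || is.null(grid) || min_size <= 1) return(sort(disp))
  inset <- logical(prod(grid)); inset[disp] <- TRUE
  seen <- logical(prod(grid)); out <- integer()
  nxy <- grid[1] * grid[2]
  for (v in disp) {
    if (seen[v]) next
    comp <- v; queue <- v; seen[v] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      co <- arrayInd(cur, grid)
      for (d in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                     c(0, 0, 1), c(0, 0, -1))) {
        nbco <- co + d
        if (any(nbco < 1) || any(nbco > grid)) next
        lin <- (nbco[3] - 1) * nxy + (nbco[2] - 1) * grid[1] + nbco[1]
        if (inset[lin] && !seen[lin]) {
          seen[lin] <- TRUE; queue <- c(queue, lin); comp <- c(comp, lin)
        }
      }
    }
    if (length(comp) >= min_size) out <- c(out, comp)
  }
  sort(out)
}

# sparse canonical weight vector by proximal gradient descent: least-squares
# fit term, soft-threshold shrinkage (lambda = phi * max |X'y|), optional
# 6-neighbour spatial smoothing of iterates, and the hard top-m sparseness
# cap; returns a unit-norm vector
fit_sparse_weights <- function(X, y, keep_frac, signs_free, smoother = identity,
                               phi = 0.25, gamma = 0.3, max_iter = 200) {
  n <- nrow(X); p <- ncol(X)
  cmu <- colMeans(X)
  Xc <- sweep(X, 2, cmu)
  yc <- y - mean(y)
  sy <- sqrt(sum(yc^2))
  if (sy < 1e-12) stop_invalid("degenerate input: constant behavior")
  yc <- yc / sy
  m <- max(1L, ceiling(keep_frac * p))
  u <- as.numeric(crossprod(Xc, yc))
  lam <- phi * max(abs(u))
  # Lipschitz constant of the fit term via power iteration on Xc'Xc
  v <- u; nv <- sqrt(sum(v^2))
  v <- if (nv > 1e-12) v / nv else rep(1 / sqrt(p), p)
  for (i in 1:15) {
    v <- as.numeric(crossprod(Xc, Xc %*% v))
    nv <- sqrt(sum(v^2)); if (nv < 1e-12) break
    v <- v / nv
  }
  L <- max(sum((Xc %*% v)^2), 1e-8)
  w <- numeric(p)
  for (it in seq_len(max_iter)) {
    g <- as.numeric(crossprod(Xc, yc - Xc %*% w))
    wn <- w + g / L
    if (gamma > 0) wn <- (1 - gamma) * wn + gamma * smoother(wn)
    wn <- sign(wn) * pmax(abs(wn) - lam / L, 0)
    wn <- project_sparse(wn, m, signs_free)
    if (max(abs(wn - w)) < 1e-9) { w <- wn; break }
    w <- wn
  }
  if (sum(w^2) == 0) w <- project_sparse(u, m, signs_free)
  w <- w / sqrt(sum(w^2))
  list(w = w, center = cmu, retained = sum(w != 0), m = m)
}

#' Sparse canonical-correlation lesion-symptom mapping
#'
#' Finds a unit-norm voxel weight vector `w` maximizing the correlation
#' between the projected lesion pattern `Xw` and the behaviour, under a
#' hard-sparsity projection that retains the top `|sparseness|` fraction of
#' weights by magnitude (alternating gradient ascent and projection from a
#' deterministic data-driven start). Following the sign convention of the
#' upstream sparse-CCA tooling, a negative `sparseness` leaves weight signs
#' unconstrained while a positive value constrains them non-negative; the
#' conventional setting -0.3 therefore keeps 30% of voxels with free signs.
#'
#' Significance is assessed by k-fold cross-validation: `cv_correlation` is
#' the Pearson correlation between pooled held-out predictions and the
#' observed behaviour, with a one-tailed t-test p-value on n - 2 df (an
#' optional permutation test is available via `n_perm`). Voxels with
#' negative weights whose normalized magnitude `|w|/max|w|` exceeds
#' `display_cut` form `displayed_voxels` -- the damage-predicts-deficit
#' voxels shown on result maps.
#'
#' @param lesion_matrix subjects x voxels binary matrix (columns already
#'   coverage-filtered; see [voxel_coverage_filter()]). Column names should
#'   be the linear voxel indices when `grid` is supplied.
#' @param behavior numeric vector, lesion-size-residualized, non-constant.
#' @param sparseness in `[-1, 1]`, magnitude = fraction of voxels retained.
#' @param folds cross-validation folds.
#' @param seed integer seed (fold assignment, stability subsamples,
#'   permutations).
#' @param grid optional grid dimensions (3 integers) enabling the spatial
#'   smoothing step and cluster pruning of the display set.
#' @param display_cut unit-norm weight display threshold (default 0.1).
#' @param n_perm optional number of permutations for a permutation p-value
#'   (0 = analytic p only).
#' @param stability_b subsample refits used to stabilize the display set
#'   (0 disables stability selection).
#' @param stability_threshold minimum selection frequency across subsamples.
#' @param min_cluster smallest displayed cluster retained when `grid` is
#'   given.
#' @return object of class `lsm_result`: `weights` (named nonzero weights of
#'   the unit-norm full-data solution), `cv_correlation`, `p`, `perm_p` (if
#'   requested), `sparseness`, `folds`, `seed`, `displayed_voxels`
#'   (character voxel indices), `retained`.
#' @export
sparse_cca_lsm <- function(lesion_matrix, behavior, sparseness = -0.3,
                           folds = 4, seed = 1, grid = NULL,
                           display_cut = 0.1, n_perm = 0,
                           stability_b = 25, stability_threshold = 0.4,
                           min_cluster = 3) {
  X <- as.matrix(lesion_matrix)
  if (!ncol(X)) stop_invalid("empty voxel set")
  if (length(behavior) != nrow(X)) stop_invalid("behavior misaligned with matrix")
  if (stats::sd(behavior) == 0) stop_invalid("degenerate input: constant behavior")
  if (abs(sparseness) > 1 || sparseness == 0)
    stop_invalid("sparseness must lie in [-1, 1], non-zero")
  if (is.null(colnames(X))) colnames(X) <- as.character(seq_len(ncol(X)))
  keep <- abs(sparseness); signs_free <- sparseness < 0
  n <- nrow(X)
  smoother <- make_mask_smoother(as.integer(colnames(X)), grid)
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  pred <- rep(NA_real_, n)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    if (sum(tr) < 3 || sum(!tr) < 1) next
    fitf <- fit_sparse_weights(X[tr, , drop = FALSE], behavior[tr],
                               keep, signs_free, smoother)
    pred[!tr] <- sweep(X[!tr, , drop = FALSE], 2, fitf$center) %*% fitf$w
  }
  ok <- is.finite(pred)
  cvr <- if (sum(ok) > 2 && stats::sd(pred[ok]) > 0)
    stats::cor(pred[ok], behavior[ok]) else 0
  df <- sum(ok) - 2L
  tstat <- cvr * sqrt(df / max(1 - cvr^2, .Machine$double.eps))
  p <- stats::pt(tstat, df, lower.tail = FALSE)
  perm_p <- NULL
  if (n_perm > 0) {
    perm_r <- vapply(seq_len(n_perm), function(b) {
      yb <- with_seed(child_seed(seed, b), sample(behavior))
      cv_corr_only(X, yb, keep, signs_free, smoother, folds,
                   child_seed(seed, b))
    }, numeric(1))
    perm_p <- (1 + sum(perm_r >= cvr)) / (1 + n_perm)
  }
  full <- fit_sparse_weights(X, behavior, keep, signs_free, smoother)
  w <- full$w
  names(w) <- colnames(X)
  displayed_w <- w < 0 & abs(w) > display_cut
  if (stability_b > 0) {
    sel <- numeric(ncol(X))
    sub_n <- max(3L, round(0.8 * n))
    for (b in seq_len(stability_b)) {
      idx <- with_seed(child_seed(seed, 500 + b), sample(n, sub_n))
      fb <- fit_sparse_weights(X[idx, , drop = FALSE], behavior[idx],
                               keep, signs_free, smoother)
      sel <- sel + (fb$w < 0 & abs(fb$w) > display_cut)
    }
    displayed_w <- sel / stability_b >= stability_threshold
  }
  displayed <- colnames(X)[displayed_w]
  if (!is.null(grid))
    displayed <- as.character(prune_clusters(as.integer(displayed), grid,
                                             min_cluster))
  nz <- w[w != 0]
  structure(list(weights = nz, cv_correlation = cvr, p = p, perm_p = perm_p,
                 sparseness = sparseness, folds = folds, seed = seed,
                 displayed_voxels = displayed, retained = full$retained,
                 display_cut = display_cut),
            class = "lsm_result")
}

cv_corr_only <- function(X, y, keep, signs_free, smoother, folds, seed) {
  n <- nrow(X)
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  pred <- rep(NA_real_, n)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    if (sum(tr) < 3 || sum(!tr) < 1) next
    fitf <- fit_sparse_weights(X[tr, , drop = FALSE], y[tr], keep,
                               signs_free, smoother)
    pred[!tr] <- sweep(X[!tr, , drop = FALSE], 2, fitf$center) %*% fitf$w
  }
  ok <- is.finite(pred)
  if (sum(ok) > 2 && stats::sd(pred[ok]) > 0) stats::cor(pred[ok], y[ok]) else 0
}

#' @export
print.lsm_result <- function(x, ...) {
  cat(sprintf(paste0("Sparse-CCA LSM: CV correlation = %.3f (one-tailed p = %.4g)",
                     "; %d voxels retained, %d displayed (negative, |w|>%.2f)\n"),
              x$cv_correlation, x$p, x$retained,
              length(x$displayed_voxels), x$display_cut))
  invisible(x)
}

#' Verdict rule for predictive validity comparison
#'
#' @param aic_difference `aic_single - aic_two`.
#' @return `"two_maps"` when the difference exceeds 100, else
#'   `"single_map"`.
#' @export
pvc_verdict <- function(aic_difference) {
  if (aic_difference > 100) "two_maps" else "single_map"
}

#' Predictive validity comparison of two behaviours
#'
#' Tests whether two behaviours are better described by one shared lesion
#' map or two distinct maps. The single-map model fits one sparse weight
#' vector on the stacked data (both behaviours, shared weights); the
#' two-map model fits each behaviour separately. Residuals come from
#' cross-validated predictions (per fold, held-out projections `Xw` are
#' calibrated onto the behaviour scale by a train-set intercept+slope
#' regression). Per model, `AIC = sum over behaviours of n*ln(RSS/n) + 2k`
#' with `k` = number of fitted maps times the retained-voxel count of the
#' sparsity projection; the two-map verdict requires
#' `aic_single - aic_two > 100`.
#'
#' @param lesion_matrix subjects x voxels binary matrix.
#' @param behavior_1,behavior_2 aligned numeric vectors (standardized,
#'   lesion-size-residualized).
#' @param sparseness,folds,seed,grid as in [sparse_cca_lsm()].
#' @return object of class `pvc_result`: `aic_single`, `aic_two`,
#'   `aic_difference`, `verdict`.
#' @export
pvc <- function(lesion_matrix, behavior_1, behavior_2, sparseness = -0.3,
                folds = 4, seed = 1, grid = NULL) {
  X <- as.matrix(lesion_matrix)
  n <- nrow(X)
  if (length(behavior_1) != n || length(behavior_2) != n)
    stop_invalid("behaviours must align with the lesion matrix subjects")
  keep <- abs(sparseness); signs_free <- sparseness < 0
  smoother <- if (!is.null(colnames(X)) && !is.null(grid))
    make_mask_smoother(as.integer(colnames(X)), grid) else identity
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  ys <- list(behavior_1, behavior_2)
  m <- max(1L, ceiling(keep * ncol(X)))

  predict_cal <- function(w, center, Xtr, ytr, Xte) {
    ztr <- as.numeric(sweep(Xtr, 2, center) %*% w)
    zte <- as.numeric(sweep(Xte, 2, center) %*% w)
    if (stats::sd(ztr) < 1e-12) return(rep(mean(ytr), nrow(Xte)))
    cf <- stats::coef(stats::lm(ytr ~ ztr))
    cf[1] + cf[2] * zte
  }

  rss_single <- c(0, 0); rss_two <- c(0, 0)
  for (f in seq_len(folds)) {
    tr <- fold_id != f; te <- !tr
    if (sum(tr) < 3 || !any(te)) next
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    # single map: one w on stacked behaviours
    fs <- fit_sparse_weights(rbind(Xtr, Xtr), c(ys[[1]][tr], ys[[2]][tr]),
                             keep, signs_free, smoother)
    for (b in 1:2) {
      pb <- predict_cal(fs$w, fs$center, Xtr, ys[[b]][tr], Xte)
      rss_single[b] <- rss_single[b] + sum((ys[[b]][te] - pb)^2)
      ft <- fit_sparse_weights(Xtr, ys[[b]][tr], keep, signs_free, smoother)
      pt2 <- predict_cal(ft$w, ft$center, Xtr, ys[[b]][tr], Xte)
      rss_two[b] <- rss_two[b] + sum((ys[[b]][te] - pt2)^2)
    }
  }
  aic_single <- sum(n * log(rss_single / n)) + 2 * m
  aic_two <- sum(n * log(rss_two / n)) + 2 * (2 * m)
  diff <- aic_single - aic_two
  structure(list(aic_single = aic_single, aic_two = aic_two,
                 aic_difference = diff, verdict = pvc_verdict(diff)),
            class = "pvc_result")
}

#' @export
print.pvc_result <- function(x, ...) {
  cat(sprintf("PVC: AIC single = %.1f, two = %.1f, difference = %.1f -> %s\n",
              x$aic_single, x$aic_two, x$aic_difference, x$verdict))
  invisible(x)
}

#' Label an LSM weight map against an atlas
#'
#' Reports, per atlas region, the share of total absolute weight mass
#' falling inside the region, filtered at shares above 10% (the reporting
#' convention for result-map summaries). Voxels claimed by several regions
#' are assigned to the first region listing them, so shares over all
#' regions plus the unlabelled remainder sum to one.
#'
#' @param result an `lsm_result`.
#' @param atlas a [tract_atlas()] (or any named list of voxel index sets
#'   wrapped as one) on the grid the lesion matrix came from.
#' @param min_share report regions above this share (default 0.10).
#' @return data.frame with columns `region`, `share`, sorted descending;
#'   zero rows for an empty weight map.
#' @export
label_weights <- function(result, atlas, min_share = 0.10) {
  stopifnot(inherits(result, "lsm_result"), inherits(atlas, "tract_atlas"))
  w <- abs(result$weights)
  if (!length(w) || sum(w) == 0)
    return(data.frame(region = character(), share = numeric()))
  vox <- as.integer(names(w))
  assigned <- rep(NA_character_, length(vox))
  for (nm in names(atlas$tracts)) {
    hit <- is.na(assigned) & vox %in% atlas$tracts[[nm]]
    assigned[hit] <- nm
  }
  total <- sum(w)
  shares <- vapply(names(atlas$tracts),
                   function(nm) sum(w[which(assigned == nm)]) / total,
                   numeric(1))
  out <- data.frame(region = names(shares), share = unname(shares))
  out <- out[out$share > min_share, , drop = FALSE]
  out[order(-out$share), , drop = FALSE]
}

#' Read and write lesion volumes as NIfTI
#'
#' Thin wrappers over RNifti; data are binarized at 0.5 on read.
#'
#' @param path NIfTI file path.
#' @param space_tag template identifier to attach on read.
#' @return [lesion_volume()] (read) or `path` invisibly (write).
#' @export
read_lesion_nifti <- function(path, space_tag = "user-space") {
  img <- RNifti::readNifti(path)
  vx <- attr(img, "pixdim")[1:3] %||% c(1, 1, 1)
  lesion_volume(array(as.numeric(img), dim = dim(img)[1:3]),
                voxel_size_mm = vx, space_tag = space_tag)
}

#' @rdname read_lesion_nifti
#' @param volume a [lesion_volume()] to write.
#' @export
write_lesion_nifti <- function(volume, path) {
  img <- RNifti::asNifti(array(as.numeric(volume$data), dim = dim(volume$data)))
  RNifti::pixdim(img) <- volume$voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read/write tract atlases and streamline sets as JSON
#'
#' Voxel indices are stored 1-based, grid-ordered (R array order), with the
#' grid dimensions alongside.
#'
#' @param path JSON file.
#' @return the corresponding container.
#' @export
read_tract_atlas_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  tract_atlas(as.list(raw$tracts), raw$grid)
}

#' @rdname read_tract_atlas_json
#' @param atlas a [tract_atlas()].
#' @export
write_tract_atlas_json <- function(atlas, path) {
  jsonlite::write_json(list(grid = atlas$grid, tracts = atlas$tracts),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname read_tract_atlas_json
#' @export
read_streamlines_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  streamline_set(as.list(raw$streamlines), raw$grid)
}

#' @rdname read_tract_atlas_json
#' @param streamlines a [streamline_set()].
#' @export
write_streamlines_json <- function(streamlines, path) {
  jsonlite::write_json(list(grid = streamlines$grid,
                            streamlines = streamlines$streamlines),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
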