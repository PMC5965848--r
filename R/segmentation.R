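#' Random-walker segmentation parameters
#'
#' Tuning knobs of the seeded random-walker segmentation. The walker moves
#' on the voxel lattice with edge weights `exp(-beta * (g_i - g_j)^2)`
#' computed from intensities min-max normalized over the region of
#' interest, so `beta` is scale-free: it controls how strongly intensity
#' edges block the walk. The probability map is cut at `prob_threshold` to
#' produce the binary lesion mask.
#'
#' @param beta edge-weight sharpness, > 0. Default 90, the customary value
#'   for random-walker segmentation on normalized intensities.
#' @param prob_threshold cut on the target probability, in (0, 1). Default
#'   0.5, the symmetric choice for two labels.
#' @param connectivity lattice neighborhood: 6 (faces), 18 (+edges) or
#'   26 (+corners). Default 6, the smallest stencil.
#' @param auto_target_fraction fraction of the ROI maximum above which a
#'   voxel becomes a target seed under automatic seeding, in (0, 1).
#' @param auto_background_shell thickness (voxels) of the ROI boundary
#'   shell used as background seeds.
#' @param solver_tolerance relative residual for the iterative linear solve
#'   (used above `direct_limit` unknowns; below it the solve is a direct
#'   sparse factorization and the tolerance is moot).
#' @param direct_limit unknown-count threshold between the direct and the
#'   conjugate-gradient solver.
#' @return An object of class `rw_params`.
#' @export
rw_params <- function(beta = 90, prob_threshold = 0.5,
                      connectivity = c(6, 18, 26),
                      auto_target_fraction = 0.90,
                      auto_background_shell = 1,
                      solver_tolerance = 1e-8,
                      direct_limit = 1e5) {
  connectivity <- as.integer(connectivity)[1]
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("'connectivity' must be 6, 18 or 26")
  if (!is.numeric(beta) || beta <= 0) stop("'beta' must be > 0")
  if (prob_threshold <= 0 || prob_threshold >= 1)
    stop("'prob_threshold' must be strictly inside (0, 1)")
  if (auto_target_fraction <= 0 || auto_target_fraction >= 1)
    stop("'auto_target_fraction' must be strictly inside (0, 1)")
  if (auto_background_shell < 1)
    stop("'auto_background_shell' must be >= 1")
  structure(list(beta = beta, prob_threshold = prob_threshold,
                 connectivity = connectivity,
                 auto_target_fraction = auto_target_fraction,
                 auto_background_shell = as.integer(auto_background_shell),
                 solver_tolerance = solver_tolerance,
                 direct_limit = direct_limit),
            class = "rw_params")
}

# half-space neighbor offsets (each undirected lattice edge listed once)
.lattice_offsets <- function(connectivity) {
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  ord <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  offs <- offs[ord <= switch(as.character(connectivity),
                             "6" = 1, "18" = 2, "26" = 3), ]
  keep <- offs$dz > 0 | (offs$dz == 0 & offs$dy > 0) |
    (offs$dz == 0 & offs$dy == 0 & offs$dx > 0)
  as.matrix(offs[keep, , drop = FALSE])
}

#' Build the lattice edge weights for the random walker
#'
#' Voxel intensities are min-max normalized over the supplied (sub)volume;
#' the weight of the edge between neighbors i and j is
#' `exp(-beta * (g_i - g_j)^2)`, symmetric, in (0, 1], and exactly 1 for
#' equal intensities. A constant region yields all-1 weights (the walk
#' becomes isotropic); an empty region is rejected.
#'
#' @param values 3D numeric array of voxel values (typically an ROI
#'   subvolume in SUV units).
#' @param params an [rw_params()].
#' @return An object of class `rw_weights`: an edge list with fields `i`,
#'   `j` (linear voxel indices), `w` (weights) and `dim`.
#' @export
build_weights <- function(values, params = rw_params()) {
  if (inherits(values, "image_volume")) values <- values$values
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array")
  if (length(values) == 0L) stop("empty region of interest")
  if (!all(is.finite(values))) stop("voxel values must be finite")
  d <- dim(values)
  rng <- range(values)
  g <- if (rng[2] > rng[1]) (values - rng[1]) / (rng[2] - rng[1])
       else array(0, d)
  idx <- array(seq_len(prod(d)), d)
  offs <- .lattice_offsets(params$connectivity)
  ii <- jj <- ww <- vector("list", nrow(offs))
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    sx <- seq_len(d[1] - abs(o[1])) + max(0, -o[1])
    sy <- seq_len(d[2] - abs(o[2])) + max(0, -o[2])
    sz <- seq_len(d[3] - abs(o[3])) + max(0, -o[3])
    if (!length(sx) || !length(sy) || !length(sz)) next
    # as.vector: single-width slices would otherwise collapse to an index
    # matrix, which `[` interprets as coordinate rows
    src <- as.vector(idx[sx, sy, sz])
    dst <- as.vector(idx[sx + o[1], sy + o[2], sz + o[3]])
    ii[[r]] <- src
    jj[[r]] <- dst
    ww[[r]] <- exp(-params$beta * (g[src] - g[dst])^2)
  }
  structure(list(i = unlist(ii), j = unlist(jj), w = unlist(ww), dim = d),
            class = "rw_weights")
}

# sparse graph Laplacian L = D - W from an rw_weights edge list
.laplacian <- function(wt) {
  n <- prod(wt$dim)
  W <- Matrix::sparseMatrix(i = c(wt$i, wt$j), j = c(wt$j, wt$i),
                            x = c(wt$w, wt$w), dims = c(n, n))
  Matrix::Diagonal(n, Matrix::rowSums(W)) - W
}

#' Seed map constructor
#'
#' @param labels integer 3D array: 0 unlabeled, 1 background, 2 target.
#' @return An object of class `seed_map`.
#' @export
seed_map <- function(labels) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("'labels' must be a 3D array")
  if (!all(labels %in% 0:2)) stop("seed labels must be 0, 1 or 2")
  storage.mode(labels) <- "integer"
  if (!any(labels == 2L)) stop("need at least one target seed")
  if (!any(labels == 1L)) stop("need at least one background seed")
  structure(list(labels = labels), class = "seed_map")
}

#' Automatic seed selection within a region of interest
#'
#' Target seeds are the voxels whose value reaches
#' `auto_target_fraction` of the ROI maximum; background seeds are the
#' boundary shell of the ROI box. The two sets are made disjoint and
#' non-empty: shell voxels that also satisfy the target rule are removed
#' from the background when other background voxels remain, otherwise they
#' stay background and are removed from the target set instead.
#'
#' @param values 3D array (ROI subvolume) of voxel values.
#' @param params an [rw_params()].
#' @return A [seed_map()] congruent with `values`.
#' @export
auto_seeds <- function(values, params = rw_params()) {
  if (inherits(values, "image_volume")) values <- values$values
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array")
  if (length(values) < 2L) stop("ROI too small to host disjoint seeds")
  d <- dim(values)
  tgt <- values >= params$auto_target_fraction * max(values)
  t0 <- params$auto_background_shell
  shell <- array(FALSE, d)
  for (ax in 1:3) {
    lo <- seq_len(min(t0, d[ax]))
    hi <- d[ax] + 1 - lo
    switch(ax,
           { shell[lo, , ] <- TRUE; shell[hi, , ] <- TRUE },
           { shell[, lo, ] <- TRUE; shell[, hi, ] <- TRUE },
           { shell[, , lo] <- TRUE; shell[, , hi] <- TRUE })
  }
  bg <- shell & !tgt
  if (!any(bg)) {            # e.g. uniform ROI: keep shell as background
    bg <- shell
    tgt <- tgt & !shell
  }
  if (!any(tgt))
    stop("ROI too small to host disjoint target and background seeds")
  labels <- array(0L, d)
  labels[bg] <- 1L
  labels[tgt] <- 2L
  seed_map(labels)
}

# connected components of a logical array under the given lattice
# connectivity; returns an integer array (0 outside, component id inside)
.components <- function(mask, connectivity) {
  d <- dim(mask)
  offs <- .lattice_offsets(connectivity)
  offs <- rbind(offs, -offs)
  comp <- array(0L, d)
  queue <- integer(sum(mask))
  nextid <- 0L
  lin <- which(mask)
  for (start in lin) {
    if (comp[start] != 0L) next
    nextid <- nextid + 1L
    comp[start] <- nextid
    queue[1] <- start
    head <- 1L; tail <- 1L
    while (head <= tail) {
      cur <- queue[head]; head <- head + 1L
      k <- (cur - 1L) %/% (d[1] * d[2])
      rem <- (cur - 1L) %% (d[1] * d[2])
      j <- rem %/% d[1]
      i <- rem %% d[1]
      for (r in seq_len(nrow(offs))) {
        ni <- i + offs[r, 1]; nj <- j + offs[r, 2]; nk <- k + offs[r, 3]
        if (ni < 0 || ni >= d[1] || nj < 0 || nj >= d[2] ||
            nk < 0 || nk >= d[3]) next
        nb <- 1L + ni + d[1] * (nj + d[2] * nk)
        if (mask[nb] && comp[nb] == 0L) {
          comp[nb] <- nextid
          tail <- tail + 1L
          queue[tail] <- nb
        }
      }
    }
  }
  comp
}

# Jacobi-preconditioned conjugate gradient for sparse SPD systems
.cg_solve <- function(A, b, tol) {
  x <- numeric(length(b))
  r <- b
  dinv <- 1 / Matrix::diag(A)
  z <- dinv * r
  p <- z
  rz <- sum(r * z)
  b2 <- sqrt(sum(b^2))
  if (b2 == 0) return(x)
  for (it in seq_len(10L * length(b))) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r^2)) / b2 < tol) break
    z <- dinv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  x
}

#' Solve the random-walker Dirichlet problem
#'
#' Computes, for every unlabeled voxel, the probability that a random walk
#' on the intensity-weighted lattice reaches a target seed before a
#' background seed. Equivalently it solves the combinatorial Dirichlet
#' problem: each unlabeled voxel's probability is the weight-averaged mean
#' of its neighbors' probabilities, with boundary values 1 at target seeds
#' and 0 at background seeds. Because the problem has two labels, one
#' solve suffices: the background probability is the complement.
#'
#' Unlabeled voxels in a connected component that touches no seed (possible
#' only when seeds disconnect the lattice) receive probability 0 with a
#' warning.
#'
#' @param values 3D array (ROI subvolume) of voxel values.
#' @param seeds a [seed_map()] congruent with `values`.
#' @param params an [rw_params()].
#' @return An object of class `probability_map`: list with `prob` (3D
#'   array in `[0, 1]`, exactly 1 at target and 0 at background seeds) and
#'   `seeds`.
#' @export
solve_rw <- function(values, seeds, params = rw_params()) {
  if (inherits(values, "image_volume")) values <- values$values
  stopifnot(inherits(seeds, "seed_map"))
  if (!identical(dim(values), dim(seeds$labels)))
    stop("volume and seed map shapes differ")
  lab <- seeds$labels
  prob <- array(0, dim(lab))
  prob[lab == 2L] <- 1
  un <- which(lab == 0L)
  if (length(un) == 0L)
    return(structure(list(prob = prob, seeds = seeds),
                     class = "probability_map"))
  wt <- build_weights(values, params)
  L <- .laplacian(wt)
  # unlabeled components reachable from a seed: those whose Dirichlet block
  # is non-singular
  umask <- array(lab == 0L, dim(lab))
  comp <- .components(umask, params$connectivity)
  # a component is seeded iff some member has an edge to a seed
  seeded_edge <- (lab[wt$i] == 0L & lab[wt$j] != 0L)
  touched <- unique(comp[wt$i[seeded_edge]])
  seeded_edge2 <- (lab[wt$j] == 0L & lab[wt$i] != 0L)
  touched <- unique(c(touched, comp[wt$j[seeded_edge2]]))
  orphan <- setdiff(unique(comp[un]), touched)
  if (length(orphan)) {
    warning(sum(comp[un] %in% orphan),
            " unlabeled voxel(s) unreachable from any seed; ",
            "assigned probability 0")
    un <- un[!comp[un] %in% orphan]
  }
  if (length(un)) {
    sdx <- which(lab != 0L)
    b <- as.numeric(lab[sdx] == 2L)
    Luu <- L[un, un, drop = FALSE]
    Lub <- L[un, sdx, drop = FALSE]
    rhs <- -as.numeric(Lub %*% b)
    # symmetric diagonal (Jacobi) scaling: at high beta a voxel whose
    # incident edges are all ~exp(-beta) makes the raw system arbitrarily
    # ill-conditioned although the probabilities stay O(1)
    s <- 1 / sqrt(Matrix::diag(Luu))
    S <- Matrix::Diagonal(x = s)
    A <- Matrix::forceSymmetric(S %*% Luu %*% S)
    rhs_s <- s * rhs
    y <- if (length(un) <= params$direct_limit)
      tryCatch(as.numeric(Matrix::solve(A, rhs_s)),
               error = function(e) .cg_solve(A, rhs_s,
                                             params$solver_tolerance))
    else .cg_solve(A, rhs_s, params$solver_tolerance)
    prob[un] <- pmin(pmax(s * y, 0), 1)  # clip float residue at the bounds
  }
  structure(list(prob = prob, seeds = seeds), class = "probability_map")
}

#' Threshold a probability map into a lesion mask
#'
#' The mask keeps the voxels whose target probability strictly exceeds the
#' threshold; since the threshold lies in (0, 1), target seeds (probability
#' exactly 1) are always kept and background seeds (exactly 0) never are.
#' Raising the threshold can only shrink the mask.
#'
#' @param pm a `probability_map` from [solve_rw()].
#' @param params an [rw_params()]; only `prob_threshold` is used.
#' @param spacing voxel spacing (mm) to attach to the mask.
#' @return A [lesion_mask()].
#' @export
threshold_map <- function(pm, params = rw_params(), spacing = c(1, 1, 1)) {
  stopifnot(inherits(pm, "probability_map"))
  lesion_mask(pm$prob > params$prob_threshold, spacing = spacing)
}

#' Rectangular region of interest
#'
#' A 0-based half-open voxel box `[lo, hi)`, the convention used on the
#' command line; converted internally to 1-based inclusive R indices.
#'
#' @param lo,hi integer length-3 corners, `lo < hi`.
#' @return An object of class `roi_box`.
#' @export
roi_box <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (length(lo) != 3L || length(hi) != 3L || any(hi <= lo))
    stop("'lo' and 'hi' must be length-3 with hi > lo (0-based half-open)")
  if (any(lo < 0)) stop("ROI corners must be >= 0")
  structure(list(lo = lo, hi = hi), class = "roi_box")
}

#' Bounding-box ROI of a mask, with padding
#'
#' @param mask a [lesion_mask()].
#' @param pad margin in voxels added on every side (clipped to the grid).
#' @return An [roi_box()].
#' @export
mask_bbox <- function(mask, pad = 3L) {
  stopifnot(inherits(mask, "lesion_mask"))
  if (!any(mask$values)) stop("empty mask has no bounding box")
  w <- which(mask$values, arr.ind = TRUE)
  d <- dim(mask$values)
  lo <- pmax(apply(w, 2, min) - 1L - pad, 0L)
  hi <- pmin(apply(w, 2, max) + pad, d)
  roi_box(lo, hi)
}

# extract the ROI subvolume of an array (1-based slices from a roi_box)
.roi_slice <- function(arr, roi) {
  d <- dim(arr)
  if (any(roi$hi > d)) stop("ROI extends outside the volume")
  arr[(roi$lo[1] + 1):roi$hi[1],
      (roi$lo[2] + 1):roi$hi[2],
      (roi$lo[3] + 1):roi$hi[3], drop = FALSE]
}

#' Segment one lesion inside an ROI box
#'
#' End-to-end seeded random-walker segmentation: automatic seed selection
#' in the ROI, Dirichlet solve, probability threshold. The returned mask
#' and probability map are congruent with the full input volume (zero
#' outside the ROI). One connected lesion per ROI is assumed; segment
#' multiple lesions by calling once per ROI.
#'
#' @param vol an [image_volume()] (SUV units recommended; only intensity
#'   contrast matters).
#' @param roi an [roi_box()]; defaults to the whole volume.
#' @param params an [rw_params()].
#' @param seeds optional [seed_map()] congruent with the ROI subvolume,
#'   overriding automatic seeding.
#' @return An object of class `rw_segmentation`: list with `mask`
#'   (full-grid [lesion_mask()]), `prob` (full-grid array), `seeds`,
#'   `roi`, `params`.
#' @export
#' @examples
#' sp <- phantom_spec(c(24, 24, 24), lesions = list(
#'   list(center = c(12, 12, 12), semi_axes = 4, uptake_contrast = 8)))
#' ph <- make_phantom(sp, seed = 1)
#' seg <- segment_lesion(ph$volume, mask_bbox(ph$truth, pad = 4))
#' seg
segment_lesion <- function(vol, roi = NULL, params = rw_params(),
                           seeds = NULL) {
  stopifnot(inherits(vol, "image_volume"))
  d <- dim(vol$values)
  if (is.null(roi)) roi <- roi_box(c(0, 0, 0), d)
  sub <- .roi_slice(vol$values, roi)
  if (is.null(seeds)) seeds <- auto_seeds(sub, params)
  pm <- solve_rw(sub, seeds, params)
  sub_mask <- pm$prob > params$prob_threshold
  full_mask <- array(FALSE, d)
  full_prob <- array(0, d)
  xr <- (roi$lo[1] + 1):roi$hi[1]
  yr <- (roi$lo[2] + 1):roi$hi[2]
  zr <- (roi$lo[3] + 1):roi$hi[3]
  full_mask[xr, yr, zr] <- sub_mask
  full_prob[xr, yr, zr] <- pm$prob
  structure(list(mask = lesion_mask(full_mask, spacing = vol$spacing),
                 prob = full_prob, seeds = seeds, roi = roi,
                 params = params),
            class = "rw_segmentation")
}

#' @export
print.rw_segmentation <- function(x, ...) {
  n <- sum(x$mask$values)
  cat("Random-walker segmentation\n")
  cat("  ROI: [", paste(x$roi$lo, collapse = ","), ") -> [",
      paste(x$roi$hi, collapse = ","), ")  beta = ", x$params$beta,
      ", p = ", x$params$prob_threshold, ", ",
      x$params$connectivity, "-connected\n", sep = "")
  cat("  seeds: ", sum(x$seeds$labels == 2L), " target, ",
      sum(x$seeds$labels == 1L), " background\n", sep = "")
  cat("  mask: ", n, " voxels (",
      format(n * prod(x$mask$spacing)), " mm^3)\n", sep = "")
  invisible(x)
}

#' @export
plot.rw_segmentation <- function(x, slice = NULL, ...) {
  d <- dim(x$prob)
  if (is.null(slice)) {
    w <- which(x$mask$values, arr.ind = TRUE)
    slice <- if (nrow(w)) round(mean(w[, 3])) else round(d[3] / 2)
  }
  graphics::image(seq_len(d[1]), seq_len(d[2]), x$prob[, , slice],
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "x (voxel)", ylab = "y (voxel)",
                  main = paste0("target probability, slice z = ", slice),
                  ...)
  graphics::contour(seq_len(d[1]), seq_len(d[2]),
                    x$mask$values[, , slice] + 0, levels = 0.5,
                    add = TRUE, drawlabels = FALSE, col = "white")
  invisible(x)
}
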