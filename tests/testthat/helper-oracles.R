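# Independent brute-force oracles used to validate the fast implementations.
# These deliberately share no code with the package internals.

# absorbing-Markov-chain solution of the seeded random walk by dense
# fundamental-matrix inversion: P(absorb at target) for every voxel
oracle_rw_dense <- function(values, labels, beta = 90, connectivity = 6) {
  d <- dim(values)
  n <- prod(d)
  rng <- range(values)
  g <- if (rng[2] > rng[1]) (values - rng[1]) / (rng[2] - rng[1])
       else array(0, d)
  coords <- arrayInd(seq_len(n), d)
  maxsum <- switch(as.character(connectivity), "6" = 1, "18" = 2, "26" = 3)
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dd <- abs(coords[i, ] - coords[j, ])
      if (max(dd) <= 1 && sum(dd) >= 1 && sum(dd) <= maxsum) {
        w <- exp(-beta * (g[i] - g[j])^2)
        W[i, j] <- w
        W[j, i] <- w
      }
    }
  }
  P <- W / rowSums(W)
  un <- which(labels == 0L)
  sd <- which(labels != 0L)
  b <- as.numeric(labels[sd] == 2L)
  probs <- array(0, d)
  probs[labels == 2L] <- 1
  if (length(un)) {
    Q <- P[un, un, drop = FALSE]
    R <- P[un, sd, drop = FALSE]
    probs[un] <- solve(diag(length(un)) - Q, as.numeric(R %*% b))
  }
  probs
}

# brute-force edge weights: double loop over all voxel pairs
oracle_weights_dense <- function(values, beta = 90, connectivity = 6) {
  d <- dim(values)
  n <- prod(d)
  rng <- range(values)
  g <- if (rng[2] > rng[1]) (values - rng[1]) / (rng[2] - rng[1])
       else array(0, d)
  coords <- arrayInd(seq_len(n), d)
  maxsum <- switch(as.character(connectivity), "6" = 1, "18" = 2, "26" = 3)
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dd <- abs(coords[i, ] - coords[j, ])
      if (max(dd) <= 1 && sum(dd) >= 1 && sum(dd) <= maxsum) {
        w <- exp(-beta * (g[i] - g[j])^2)
        W[i, j] <- w
        W[j, i] <- w
      }
    }
  }
  W
}

# Mann-Whitney AUC by exhaustive pair counting (ties count one half);
# lower scores call positive when direction == "lower"
oracle_auc_pairs <- function(score, is_responder, direction = "lower") {
  pos <- score[as.logical(is_responder)]
  neg <- score[!as.logical(is_responder)]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      ordered <- if (direction == "lower") p < q else p > q
      tot <- tot + if (p == q) 0.5 else as.numeric(ordered)
    }
  }
  tot / (length(pos) * length(neg))
}

# full enumeration of the two-sided label-permutation null for the AUC
oracle_perm_pvalue <- function(score, is_responder, direction = "lower") {
  n <- length(score)
  n_pos <- sum(is_responder)
  obs <- abs(oracle_auc_pairs(score, is_responder, direction) - 0.5)
  combos <- combn(n, n_pos)
  stat <- apply(combos, 2, function(ix) {
    lab <- logical(n)
    lab[ix] <- TRUE
    abs(oracle_auc_pairs(score, lab, direction) - 0.5)
  })
  mean(stat >= obs - 1e-12)
}

# lattice points whose center lies inside the ellipsoid, by enumeration
oracle_ellipsoid_count <- function(semi_axes_mm, spacing = c(1, 1, 1),
                                   center = c(0, 0, 0)) {
  if (length(semi_axes_mm) == 1) semi_axes_mm <- rep(semi_axes_mm, 3)
  r <- ceiling(semi_axes_mm / spacing) + 1
  count <- 0L
  for (i in -r[1]:r[1]) {
    for (j in -r[2]:r[2]) {
      for (k in -r[3]:r[3]) {
        q <- ((i * spacing[1] - center[1]) / semi_axes_mm[1])^2 +
          ((j * spacing[2] - center[2]) / semi_axes_mm[2])^2 +
          ((k * spacing[3] - center[3]) / semi_axes_mm[3])^2
        if (q <= 1) count <- count + 1L
      }
    }
  }
  count
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Random small seeded lattice instance for oracle-equivalence checks.
# beta is capped so the weakest edge stays ~e^-12: across barriers much
# weaker than that, the Dirichlet solution depends on ratios of numbers
# below double-precision resolution and no solver (sparse or dense) can
# pin it down, so solver-vs-oracle comparison would be meaningless there.
random_rw_instance <- function(max_dim = 4L) {
  d <- sample(2:max_dim, 3, replace = TRUE)
  values <- array(runif(prod(d)), d)
  repeat {
    labels <- array(sample(0:2, prod(d), replace = TRUE,
                           prob = c(0.6, 0.2, 0.2)), d)
    if (any(labels == 1L) && any(labels == 2L)) break
  }
  list(values = values, labels = labels, beta = runif(1, 1, 12))
}
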