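# Independent brute-force oracles. These deliberately share no code with
# the package: plain loops over voxels, neighbours and score pairs.

oracle_offsets26 <- function() {
  out <- NULL
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1)
    if (dz != 0 || dy != 0 || dx != 0) out <- rbind(out, c(dz, dy, dx))
  out
}

# levels: 3-D integer array with NA outside the ROI
oracle_in <- function(levels, p) {
  d <- dim(levels)
  all(p >= 1) && all(p <= d) && !is.na(levels[p[1], p[2], p[3]])
}

# per-direction symmetric GLCM counts; returns list of ng x ng matrices
oracle_glcm_mats <- function(levels, ng) {
  d <- dim(levels)
  offs <- oracle_offsets26()
  # unique up to sign: keep lexicographically positive
  keep <- apply(offs, 1, function(o)
    o[3] > 0 || (o[3] == 0 && o[2] > 0) || (o[3] == 0 && o[2] == 0 && o[1] > 0))
  offs <- offs[keep, , drop = FALSE]
  mats <- list()
  for (k in seq_len(nrow(offs))) {
    P <- matrix(0, ng, ng)
    for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
      if (is.na(levels[z, y, x])) next
      q <- c(z, y, x) + offs[k, ]
      if (!oracle_in(levels, q)) next
      i <- levels[z, y, x]; j <- levels[q[1], q[2], q[3]]
      P[i, j] <- P[i, j] + 1
      P[j, i] <- P[j, i] + 1
    }
    if (sum(P) > 0) mats[[length(mats) + 1]] <- P
  }
  mats
}

oracle_glcm <- function(levels, ng) {
  mats <- oracle_glcm_mats(levels, ng)
  P <- Reduce(`+`, lapply(mats, function(m) m / sum(m))) / length(mats)
  i <- row(P); j <- col(P)
  pm <- rowSums(P)
  mu <- sum(seq_len(ng) * pm)
  s2 <- sum(seq_len(ng)^2 * pm) - mu^2
  nz <- P > 0
  list(matrix = P,
       contrast = sum(P * (i - j)^2),
       correlation = if (s2 > 0) (sum(P * i * j) - mu^2) / s2 else 1,
       joint_entropy = -sum(P[nz] * log2(P[nz])),
       idm = sum(P / (1 + (i - j)^2)),
       cluster_shade = sum(P * (i + j - 2 * mu)^3))
}

oracle_gldm <- function(levels, ng, alpha = 0) {
  d <- dim(levels)
  offs <- oracle_offsets26()
  P <- matrix(0, ng, 27)
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    if (is.na(levels[z, y, x])) next
    dep <- 0
    for (k in seq_len(nrow(offs))) {
      q <- c(z, y, x) + offs[k, ]
      if (oracle_in(levels, q) &&
          abs(levels[z, y, x] - levels[q[1], q[2], q[3]]) <= alpha)
        dep <- dep + 1
    }
    P[levels[z, y, x], dep + 1] <- P[levels[z, y, x], dep + 1] + 1
  }
  N <- sum(P)
  dsize <- matrix(1:27, ng, 27, byrow = TRUE)
  p <- P / N
  nz <- P > 0
  list(matrix = P,
       sde = sum(P / dsize^2) / N,
       lde = sum(P * dsize^2) / N,
       gln = sum(rowSums(P)^2) / N,
       dep_entropy = -sum(p[nz] * log2(p[nz])))
}

# zones by repeated expansion over an explicit visited set (flood fill)
oracle_glszm_zones <- function(levels) {
  d <- dim(levels)
  offs <- oracle_offsets26()
  visited <- array(FALSE, d)
  zones <- NULL
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    if (is.na(levels[z, y, x]) || visited[z, y, x]) next
    lev <- levels[z, y, x]
    members <- matrix(c(z, y, x), 1)
    visited[z, y, x] <- TRUE
    repeat {
      grew <- FALSE
      for (r in seq_len(nrow(members))) {
        for (k in seq_len(nrow(offs))) {
          q <- members[r, ] + offs[k, ]
          if (oracle_in(levels, q) && !visited[q[1], q[2], q[3]] &&
              levels[q[1], q[2], q[3]] == lev) {
            members <- rbind(members, q)
            visited[q[1], q[2], q[3]] <- TRUE
            grew <- TRUE
          }
        }
      }
      if (!grew) break
    }
    zones <- rbind(zones, c(level = lev, size = nrow(members)))
  }
  zones
}

oracle_glszm <- function(levels, ng) {
  z <- oracle_glszm_zones(levels)
  smax <- max(z[, "size"])
  P <- matrix(0, ng, smax)
  for (r in seq_len(nrow(z)))
    P[z[r, "level"], z[r, "size"]] <- P[z[r, "level"], z[r, "size"]] + 1
  Nz <- sum(P)
  s <- matrix(seq_len(smax), ng, smax, byrow = TRUE)
  p <- P / Nz
  nz <- P > 0
  list(matrix = P,
       sae = sum(P / s^2) / Nz,
       lae = sum(P * s^2) / Nz,
       zsn = sum(colSums(P)^2) / Nz,
       zone_entropy = -sum(p[nz] * log2(p[nz])))
}

oracle_ngtdm <- function(levels, ng) {
  d <- dim(levels)
  offs <- oracle_offsets26()
  n_i <- numeric(ng); s_i <- numeric(ng)
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    if (is.na(levels[z, y, x])) next
    nb <- c()
    for (k in seq_len(nrow(offs))) {
      q <- c(z, y, x) + offs[k, ]
      if (oracle_in(levels, q)) nb <- c(nb, levels[q[1], q[2], q[3]])
    }
    if (length(nb) == 0) next
    i <- levels[z, y, x]
    n_i[i] <- n_i[i] + 1
    s_i[i] <- s_i[i] + abs(i - mean(nb))
  }
  N <- sum(n_i)
  p <- n_i / N
  act <- which(n_i > 0)
  ngp <- length(act)
  ps <- sum(p * s_i)
  contrast <- 0; busy_den <- 0; complexity <- 0; strength_num <- 0
  for (i in act) for (j in act) {
    contrast <- contrast + p[i] * p[j] * (i - j)^2
    busy_den <- busy_den + abs(i * p[i] - j * p[j])
    complexity <- complexity +
      abs(i - j) * (p[i] * s_i[i] + p[j] * s_i[j]) / (p[i] + p[j])
    strength_num <- strength_num + (p[i] + p[j]) * (i - j)^2
  }
  list(n = n_i, s = s_i, N = N,
       coarseness = if (ps > 0) 1 / ps else 1e6,
       contrast = if (ngp > 1) contrast / (ngp * (ngp - 1)) * sum(s_i) / N
                  else 0,
       busyness = if (busy_den > 0) ps / busy_den else 0,
       complexity = complexity / N,
       strength = if (sum(s_i) > 0) strength_num / sum(s_i) else 0)
}

oracle_firstorder <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  m2 <- sum((x - m)^2) / n
  m3 <- sum((x - m)^3) / n
  m4 <- sum((x - m)^4) / n
  ent <- 0
  if (max(x) > min(x)) {
    w <- (max(x) - min(x)) / 32
    bins <- floor((x - min(x)) / w) + 1
    bins[bins > 32] <- 32
    for (b in unique(bins)) {
      pb <- sum(bins == b) / n
      ent <- ent - pb * log2(pb)
    }
  }
  list(mean = m, range = max(x) - min(x), energy = sum(x^2), entropy = ent,
       sd = sqrt(m2),
       skewness = if (m2 > 0) m3 / m2^1.5 else 0,
       kurtosis = if (m2 > 0) m4 / m2^2 else 0,
       p10 = unname(quantile(x, 0.1)), p90 = unname(quantile(x, 0.9)))
}

oracle_max_diameter <- function(mask, spacing = c(1, 1, 1)) {
  idx <- which(mask == 1, arr.ind = TRUE)
  best <- 0
  for (a in seq_len(nrow(idx))) for (b in seq_len(nrow(idx))) {
    d <- sqrt(sum(((idx[a, ] - idx[b, ]) * spacing)^2))
    if (d > best) best <- d
  }
  best
}

oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

oracle_best_sens_spec <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + 1)
  best <- -Inf
  for (th in cand) {
    sens <- mean(scores[labels == 1] >= th)
    spec <- mean(scores[labels == 0] < th)
    if (sens + spec > best) best <- sens + spec
  }
  best
}

# random small discretized ROI for oracle comparisons
random_droi <- function(seed, max_dim = 6L, n_levels = 3L) {
  set.seed(seed)
  d <- sample(2:max_dim, 3, replace = TRUE)
  vol <- array(runif(prod(d)), d)
  mask <- array(rbinom(prod(d), 1, 0.6), d)
  if (sum(mask) < 2) mask[sample(prod(d), 2)] <- 1L
  suppressWarnings(discretize_roi(vol, mask, n_levels = n_levels))
}
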