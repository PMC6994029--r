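# Independent reference implementations used as oracles. These stay
# deliberately naive (loops, enumeration) and share no code with the
# package internals they check.

# random mixture-of-Gaussian-bumps histogram (1-3 bumps)
random_mixture_hist <- function() {
  nb <- sample(1:3, 1)
  v <- unlist(lapply(seq_len(nb), function(i)
    round(stats::rnorm(sample(50:400, 1), stats::runif(1, 10, 245),
                       stats::runif(1, 3, 40)))))
  v <- as.integer(pmin(pmax(v, 0), 255))
  if (length(unique(v)) < 2) v <- c(v, 0L, 255L)
  histogram_of(matrix(v, nrow = 1))
}

# intermeans fixed-point condition at t: t must reproduce itself under
# one update (means of the two classes averaged, rounded half-down,
# clamped to the occupied range)
intermeans_is_fixed_point <- function(h, t) {
  v <- 0:255
  cnt <- h$counts
  occ <- which(cnt > 0) - 1
  below <- v <= t
  mu1 <- sum(v[below] * cnt[below]) / sum(cnt[below])
  mu2 <- sum(v[!below] * cnt[!below]) / sum(cnt[!below])
  t2 <- ceiling((mu1 + mu2) / 2 - 0.5)
  t2 <- min(max(t2, min(occ)), max(occ) - 1)
  t2 == t
}

# exhaustive Kapur maximum-entropy search, naive loop
kapur_argmax_naive <- function(h) {
  p <- h$counts / h$total
  best <- -Inf
  bt <- NA_integer_
  for (t in 0:255) {
    Plo <- sum(p[1:(t + 1)])
    Phi <- 1 - Plo
    Hlo <- 0
    Hhi <- 0
    if (Plo > 0) {
      q <- p[1:(t + 1)] / Plo
      q <- q[q > 0]
      Hlo <- -sum(q * log(q))
    }
    if (Phi > 1e-15 && t < 255) {
      q <- p[(t + 2):256] / Phi
      q <- q[q > 0]
      Hhi <- -sum(q * log(q))
    }
    if (Hlo + Hhi > best + 1e-12) {
      best <- Hlo + Hhi
      bt <- t
    }
  }
  bt
}

# breadth-first flood fill component labelling (queue-based)
flood_components <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nb <- if (connectivity == 8)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  k <- 0L
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (mask[i, j] && lab[i, j] == 0L) {
      k <- k + 1L
      queue <- list(c(i, j))
      lab[i, j] <- k
      while (length(queue)) {
        cur <- queue[[1]]; queue <- queue[-1]
        for (q in seq_len(nrow(nb))) {
          r <- cur[1] + nb[q, 1]; cc <- cur[2] + nb[q, 2]
          if (r >= 1 && r <= H && cc >= 1 && cc <= W &&
              mask[r, cc] && lab[r, cc] == 0L) {
            lab[r, cc] <- k
            queue[[length(queue) + 1]] <- c(r, cc)
          }
        }
      }
    }
  }
  lab
}

# check that two label images define the same partition of the foreground
same_partition <- function(a, b) {
  fg <- a > 0
  if (!identical(fg, b > 0)) return(FALSE)
  pairs <- unique(cbind(a[fg], b[fg]))
  nrow(pairs) == length(unique(a[fg])) &&
    nrow(pairs) == length(unique(b[fg]))
}

# independent Friedman chi-square (tie-corrected), coded from the rank
# formula without reference to the package implementation
friedman_chi2_ref <- function(m) {
  n <- nrow(m); k <- ncol(m)
  r <- t(apply(m, 1, rank))
  S <- sum((colSums(r) - n * (k + 1) / 2)^2)
  num <- 12 * S
  tie <- sum(apply(m, 1, function(row) sum(table(row)^3 - table(row))))
  den <- n * k * (k + 1) - tie / (k - 1)
  num / den
}

# independent signed-rank Z
wilcoxon_z_ref <- function(a, b) {
  d <- (a - b)[a != b]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  tb <- table(r)
  s2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tb^3 - tb) / 48
  (W - mu) / sqrt(s2)
}

# seeded scene with uniformly random centres over the whole canvas;
# chromatosomes may straddle the border (kept, as in real crops)
random_scene <- function(k, class, side = 96, base_radius = 12,
                         noise_sigma = 0, seed = 1, background = "white") {
  set.seed(seed)
  chrom <- lapply(seq_len(k), function(i) chromatosome_spec(
    center = c(stats::runif(1, 0, side - 1), stats::runif(1, 0, side - 1)),
    dispersion_class = class, base_radius = base_radius,
    rotation = stats::runif(1, 0, 2 * pi)))
  scene_spec(side, side, background, chrom,
             noise_sigma = noise_sigma, seed = seed)
}

# simple deterministic grid scene: k chromatosomes of one class laid on
# a regular grid, all inside the canvas
grid_scene <- function(k, class, side = 128, base_radius = 12,
                       noise_sigma = 0, seed = 1, background = "white",
                       pigment_rgb = c(0, 0, 0)) {
  per_row <- ceiling(sqrt(k))
  gap <- (side - 2 * base_radius) / per_row
  chrom <- lapply(seq_len(k) - 1, function(i) {
    chromatosome_spec(
      center = c(base_radius + gap * (i %/% per_row + 0.5),
                 base_radius + gap * (i %% per_row + 0.5)),
      dispersion_class = class, base_radius = base_radius,
      rotation = 0.37 * i, pigment_rgb = pigment_rgb)
  })
  scene_spec(side, side, background, chrom,
             noise_sigma = noise_sigma, seed = seed)
}
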