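# Shared fixtures and independent oracles. All fixtures are built in code.

disk_mask <- function(radius, pad = 6) {
  size <- 2 * radius + 2 * pad + 1
  ctr <- radius + pad + 1
  g <- expand.grid(r = seq_len(size), c = seq_len(size))
  matrix(as.integer((g$r - ctr)^2 + (g$c - ctr)^2 <= radius^2), size, size)
}

rect_mask <- function(h, w, pad = 6) {
  m <- matrix(0L, h + 2 * pad, w + 2 * pad)
  m[pad + seq_len(h), pad + seq_len(w)] <- 1L
  m
}

# random connected blob: union of a few overlapping disks
random_blob <- function(seed, size = 80) {
  set.seed(seed)
  m <- matrix(0L, size, size)
  n <- sample(2:5, 1)
  r0 <- runif(1, size * 0.35, size * 0.65)
  c0 <- runif(1, size * 0.35, size * 0.65)
  g <- expand.grid(r = seq_len(size), c = seq_len(size))
  for (i in seq_len(n)) {
    rad <- runif(1, 4, 12)
    rr <- r0 + runif(1, -8, 8); cc <- c0 + runif(1, -8, 8)
    m[(g$r - rr)^2 + (g$c - cc)^2 <= rad^2] <- 1L
  }
  m
}

# exhaustive-rotation Feret oracle on the pixel-corner point cloud
feret_sweep <- function(mask, step_deg = 0.1) {
  idx <- which(mask > 0)
  r <- ((idx - 1) %% nrow(mask)) + 1
  c <- ((idx - 1) %/% nrow(mask)) + 1
  pts <- cbind(c(r - 0.5, r - 0.5, r + 0.5, r + 0.5),
               c(c - 0.5, c + 0.5, c - 0.5, c + 0.5))
  angles <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  widths <- vapply(angles, function(a) {
    proj <- pts[, 1] * cos(a) + pts[, 2] * sin(a)
    diff(range(proj))
  }, numeric(1))
  c(min = min(widths), max = max(widths))
}

# brute-force three-class Otsu: explicit loop over every threshold pair
otsu3_bruteforce <- function(image, nbins = 256) {
  bin <- pmin(pmax(floor(image * nbins), 0), nbins - 1)
  counts <- tabulate(bin + 1, nbins = nbins)
  centres <- seq_len(nbins) - 0.5
  W <- cumsum(counts)
  S <- cumsum(counts * centres)
  best <- c(-Inf, NA, NA)
  for (i in 1:(nbins - 2)) {
    for (j in (i + 1):(nbins - 1)) {
      w0 <- W[i]; w1 <- W[j] - W[i]; w2 <- W[nbins] - W[j]
      s0 <- S[i]; s1 <- S[j] - S[i]; s2 <- S[nbins] - S[j]
      v <- 0
      if (w0 > 0) v <- v + s0^2 / w0
      if (w1 > 0) v <- v + s1^2 / w1
      if (w2 > 0) v <- v + s2^2 / w2
      if (v > best[1]) best <- c(v, i / nbins, j / nbins)
    }
  }
  best[2:3]
}

# all permutations of 1..n (n <= 7)
all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# exact permutation p-value for Spearman's rho
spearman_exact_p <- function(x, y) {
  n <- length(x)
  obs <- cor(x, y, method = "spearman")
  perms <- all_perms(n)
  rhos <- apply(perms, 1, function(p) cor(x, y[p], method = "spearman"))
  mean(abs(rhos) >= abs(obs) - 1e-9)
}

# exact sign-assignment p-value for the Wilcoxon signed-rank statistic
signed_rank_exact_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  v <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.numeric(signs %*% rk)
  mu <- n * (n + 1) / 4
  mean(abs(vs - mu) >= abs(v - mu) - 1e-9)
}

# exact enumeration p-value for the Mann-Whitney U (conditional on ranks)
mann_whitney_exact_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  rk <- rank(c(a, b))
  u <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  picks <- utils::combn(na + nb, na)
  us <- colSums(matrix(rk[picks], nrow = na)) - na * (na + 1) / 2
  mu <- na * nb / 2
  mean(abs(us - mu) >= abs(u - mu) - 1e-9)
}

# best-match intersection-over-union of each truth object against a labeling
truth_ious <- function(truth_mask, labels) {
  vapply(seq_len(max(truth_mask)), function(i) {
    tm <- truth_mask == i
    cand <- setdiff(unique(labels[tm]), 0)
    if (!length(cand)) return(0)
    max(vapply(cand, function(l) {
      lm <- labels == l
      sum(lm & tm) / sum(lm | tm)
    }, numeric(1)))
  }, numeric(1))
}
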