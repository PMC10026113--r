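# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so generators never perturb user RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

assert_image <- function(x, arg = "image") {
  if (!is.matrix(x) || !(is.numeric(x) || is.logical(x)))
    abort(sprintf("`%s` must be a 2-D numeric matrix.", arg))
  invisible(x)
}

assert_mask <- function(x, arg = "mask") {
  assert_image(x, arg)
  if (any(x < 0)) abort(sprintf("`%s` must be non-negative.", arg))
  invisible(x)
}

# Rescale to [0, 1]; a zero-range input is returned as all zeros.
rescale01 <- function(x) {
  r <- range(x, finite = TRUE)
  if (!is.finite(r[1]) || r[2] - r[1] <= 0) return(x * 0)
  (x - r[1]) / (r[2] - r[1])
}

# 8-connected labeling built on EBImage's 4-connected bwlabel: labels that
# touch diagonally are merged with a union-find pass.
label_components <- function(mask) {
  assert_mask(mask)
  bw <- mask > 0
  if (!any(bw)) return(matrix(0L, nrow(bw), ncol(bw)))
  lab <- EBImage::bwlabel(bw)
  lab <- matrix(as.integer(round(lab)), nrow(bw), ncol(bw))
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- NULL
  if (nr > 1 && nc > 1) {
    a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]     # down-right diagonal
    a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]    # down-left diagonal
    keep1 <- a1 > 0 & b1 > 0 & a1 != b1
    keep2 <- a2 > 0 & b2 > 0 & a2 != b2
    pairs <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
  }
  n <- max(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (!is.null(pairs) && nrow(pairs)) {
    pairs <- unique(pairs)
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  remap <- match(root, sort(unique(root)))
  out <- lab
  out[out > 0] <- remap[out[out > 0]]
  out
}

# Relabel a mask so the positive labels are 1..n (order preserved).
compact_labels <- function(labels) {
  u <- sort(unique(labels[labels > 0]))
  if (!length(u)) return(matrix(0L, nrow(labels), ncol(labels)))
  out <- labels
  out[out > 0] <- match(out[out > 0], u)
  matrix(as.integer(out), nrow(labels), ncol(labels))
}

label_ids <- function(labels) sort(unique(labels[labels > 0]))

# (row, col) coordinates of the pixels of one label.
label_pixels <- function(labels, label) {
  idx <- which(labels == label)
  if (!length(idx)) abort(sprintf("label %s not present in mask", label))
  cbind(row = ((idx - 1L) %% nrow(labels)) + 1L,
        col = ((idx - 1L) %/% nrow(labels)) + 1L)
}

label_centroids <- function(labels) {
  ids <- label_ids(labels)
  if (!length(ids))
    return(tibble(label = integer(), row = numeric(), col = numeric()))
  idx <- which(labels > 0)
  lab <- labels[idx]
  r <- ((idx - 1L) %% nrow(labels)) + 1L
  c <- ((idx - 1L) %/% nrow(labels)) + 1L
  tibble(label = as.integer(names(tapply(r, lab, mean))),
         row = as.numeric(tapply(r, lab, mean)),
         col = as.numeric(tapply(c, lab, mean)))
}
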