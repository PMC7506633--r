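# Independent brute-force oracles. These deliberately use naive loops and a
# separate code path from the package internals.

# Single-level Haar decomposition by explicit per-block dot products.
oracle_dwt_level <- function(image, bank) {
  if (is.matrix(image)) dim(image) <- c(dim(image), 1L)
  d <- dim(image)
  h2 <- d[1] %/% 2L; w2 <- d[2] %/% 2L; C <- d[3]
  kernels <- list(bank$w_ll, bank$w_lh, bank$w_hl, bank$w_hh)
  out <- array(0, c(h2, w2, 4L * C))
  for (ch in seq_len(C)) {
    for (i in seq_len(h2)) {
      for (j in seq_len(w2)) {
        block <- image[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), ch]
        for (q in 1:4) {
          out[i, j, (ch - 1L) * 4L + q] <- sum(block * kernels[[q]])
        }
      }
    }
  }
  out
}

# Recursive pyramid oracle: re-applies the level oracle to the LL channels.
oracle_dwt_pyramid <- function(image, levels, bank) {
  if (is.matrix(image)) dim(image) <- c(dim(image), 1L)
  out <- vector("list", levels)
  current <- image
  for (l in seq_len(levels)) {
    s <- oracle_dwt_level(current, bank)
    out[[l]] <- s
    current <- s[, , seq.int(1L, dim(s)[3], 4L), drop = FALSE]
  }
  out
}

# AUC as the Mann-Whitney concordance probability over all pos-neg pairs,
# ties counted 1/2.
oracle_auc_pairwise <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (n in neg) {
      total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Per-item tally of the four confusion states.
oracle_confusion <- function(labels, predictions, positive_class) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(labels)) {
    actual_pos <- labels[i] == positive_class
    pred_pos <- predictions[i] == positive_class
    if (actual_pos && pred_pos) tp <- tp + 1L
    else if (!actual_pos && pred_pos) fp <- fp + 1L
    else if (!actual_pos && !pred_pos) tn <- tn + 1L
    else fn <- fn + 1L
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

random_image <- function(h, w, c = 1L) array(stats::rnorm(h * w * c), c(h, w, c))
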