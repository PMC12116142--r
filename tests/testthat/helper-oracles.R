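# Independent brute-force oracles. These stay deliberately naive: they are
# the reference the fast implementations are checked against.

# per-pixel bounding rectangles of 8-connected components via BFS flood fill
bf_mask_boxes <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  out <- list()
  for (c0 in seq_len(w)) for (r0 in seq_len(h)) {
    if (mask[r0, c0] == 0 || seen[r0, c0]) next
    queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE
    px <- matrix(NA_integer_, 0, 2)
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      px <- rbind(px, p)
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= h && c >= 1 && c <= w &&
            mask[r, c] == 1 && !seen[r, c]) {
          seen[r, c] <- TRUE
          queue <- c(queue, list(c(r, c)))
        }
      }
    }
    out[[length(out) + 1]] <- c(x_min = min(px[, 2]) - 1L, y_min = min(px[, 1]) - 1L,
                                x_max = max(px[, 2]), y_max = max(px[, 1]))
  }
  if (!length(out)) return(data.frame(x_min = numeric(), y_min = numeric(),
                                      x_max = numeric(), y_max = numeric()))
  as.data.frame(do.call(rbind, out))
}

# maximum number of IoU-feasible one-to-one matches, by exhaustive recursion
bf_max_matches <- function(M, threshold) {
  np <- nrow(M); ng <- ncol(M)
  if (np == 0 || ng == 0) return(0L)
  rec <- function(i, taken) {
    if (i > np) return(0L)
    best <- rec(i + 1L, taken)                      # leave prediction i unmatched
    for (j in seq_len(ng)) {
      if (!taken[j] && M[i, j] >= threshold) {
        t2 <- taken; t2[j] <- TRUE
        best <- max(best, 1L + rec(i + 1L, t2))
      }
    }
    best
  }
  rec(1L, rep(FALSE, ng))
}

# OLS through the normal equations, no lm()
bf_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

# brute-force tile count: place tiles until the image is covered
bf_tile_count <- function(w, h, t) {
  nc <- 0L; x <- 0L
  while (x < w) { nc <- nc + 1L; x <- x + t }
  nr <- 0L; y <- 0L
  while (y < h) { nr <- nr + 1L; y <- y + t }
  nc * nr
}

# random instance where every prediction overlaps at most one ground truth
# above any threshold: ground truths live on a coarse grid 100 px apart,
# each prediction targets one of them (or empty space)
random_match_instance <- function(seed) {
  set.seed(seed)
  ng <- sample(0:4, 1); np <- sample(0:4, 1)
  gts <- if (ng > 0)
    pixel_box(x_min = 100 * seq_len(ng), y_min = 10,
              x_max = 100 * seq_len(ng) + 20, y_max = 30)
  else pixel_box()
  if (np > 0) {
    target <- sample(0:ng, np, replace = TRUE)   # 0 = background prediction
    x0 <- ifelse(target == 0, 1000 + 50 * seq_len(np), 100 * target)
    dx <- round(runif(np, 0, 18)); dy <- round(runif(np, 0, 18))
    preds <- detections(pixel_box(x_min = x0 + dx, y_min = 10 + dy,
                                  x_max = x0 + dx + 20, y_max = 30 + dy),
                        confidence = runif(np))
  } else {
    preds <- detections(pixel_box(), numeric())
  }
  list(preds = preds, gts = gts)
}

random_mask <- function(seed, max_dim = 32L) {
  set.seed(seed)
  h <- sample(3:max_dim, 1); w <- sample(3:max_dim, 1)
  matrix(rbinom(h * w, 1, runif(1, 0.1, 0.5)), h, w)
}

# sort box rows into a canonical order for set comparison
canon_boxes <- function(b) {
  b <- as.data.frame(b)[c("x_min", "y_min", "x_max", "y_max")]
  b <- b[order(b$x_min, b$y_min, b$x_max, b$y_max), , drop = FALSE]
  rownames(b) <- NULL
  b
}
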