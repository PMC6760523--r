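# Independent brute-force oracles used to cross-check the pipeline
# primitives, deliberately written with a different algorithmic route
# than the implementations they verify.

# Sliding-window median, explicit loops, edges replicated by index clamping.
oracle_median <- function(img, k) {
  h <- k %/% 2
  nr <- nrow(img); nc <- ncol(img)
  out <- img
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- pmin(pmax(i + (-h:h), 1), nr)
    jj <- pmin(pmax(j + (-h:h), 1), nc)
    out[i, j] <- median(img[ii, jj])
  }
  out
}

# Exhaustive Otsu: evaluate the between-class variance at every candidate
# threshold, keep the smallest argmax.
oracle_otsu <- function(img) {
  v <- as.numeric(img)
  ts <- sort(unique(v))
  if (length(ts) == 1) return(list(threshold = ts, separable = FALSE))
  ts <- ts[-length(ts)]
  best_t <- NA; best_s <- -Inf
  for (t in ts) {
    g0 <- v[v <= t]; g1 <- v[v > t]
    s <- (length(g0) / length(v)) * (length(g1) / length(v)) *
      (mean(g0) - mean(g1))^2
    if (s > best_s) { best_s <- s; best_t <- t }
  }
  list(threshold = best_t, separable = TRUE)
}

# 8-connected labelling by queue-based flood fill over an R matrix.
oracle_label <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        a <- p[1] + di; b <- p[2] + dj
        if (a >= 1 && a <= nr && b >= 1 && b <= nc &&
            mask[a, b] && lab[a, b] == 0L) {
          lab[a, b] <- nxt
          queue <- c(queue, list(c(a, b)))
        }
      }
    }
  }
  lab
}

# Drop image attributes so pixel content can be compared directly.
strip_img <- function(m) {
  attributes(m) <- list(dim = dim(m))
  m
}

# A small-field optics with the same ~0.6 um object pixel pitch as the
# full-frame geometry, for fast scene renders.
optics_for <- function(extent_um, pitch_um = 0.6) {
  optics_geometry(extent_um, as.integer(round(extent_um / pitch_um)))
}

# Match detections to ground-truth cells by nearest centre; returns the
# ground-truth table with detected label (or NA) per cell.
match_detections <- function(report, scene, optics) {
  gt <- ground_truth_table(scene)
  pitch <- optics$fov_um / optics$resolution_px
  gt$detected <- NA_character_
  det <- report$cells
  if (NROW(det) == 0) return(gt)
  dx <- det$centroid_x_px * pitch[1]
  dy <- det$centroid_y_px * pitch[2]
  for (i in seq_len(nrow(gt))) {
    d <- sqrt((dx - gt$x_um[i])^2 + (dy - gt$y_um[i])^2)
    j <- which.min(d)
    if (d[j] <= gt$diameter_um[i] / 2 + 2) gt$detected[i] <- det$label[j]
  }
  gt
}

# One bright in-focus test cell without generator randomness.
fixed_cell <- function(phenotype, x, y, d, z = 0, scale = 1) {
  em <- switch(phenotype,
               CTC = c(blue = 20000, green = 8000, orange = 600, red = 0),
               WBC = c(blue = 20000, green = 0, orange = 0, red = 10000),
               NUCLEATED_OTHER = c(blue = 20000, green = 0, orange = 0,
                                   red = 0))
  ground_truth_cell(phenotype, c(x, y), d, em * scale, z)
}
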