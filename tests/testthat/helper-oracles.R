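## Independent oracles used to cross-check the package's own computations.

## brute-force: bounding box and size of the largest 4-connected component
## of a logical mask, by queue-based flood fill (independent of the
## labelling library used by the tracker)
bruteLargestComponent <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  best <- NULL
  for (r0 in seq_len(h)) for (c0 in seq_len(w)) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    queue <- matrix(c(r0, c0), ncol = 2)
    seen[r0, c0] <- TRUE
    cells <- queue
    while (nrow(queue)) {
      cur <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        r <- cur[1] + d[1]; c <- cur[2] + d[2]
        if (r >= 1 && r <= h && c >= 1 && c <= w && mask[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          queue <- rbind(queue, c(r, c))
          cells <- rbind(cells, c(r, c))
        }
      }
    }
    if (is.null(best) || nrow(cells) > best$size)
      best <- list(size = nrow(cells),
                   x0 = min(cells[, 2]) - 1, x1 = max(cells[, 2]) - 1,
                   y0 = min(cells[, 1]) - 1, y1 = max(cells[, 1]) - 1)
  }
  best
}

## brute-force joint entropy by direct enumeration of occupied cells,
## using cut()/table() rather than the package's index arithmetic
jointEntropyOracle <- function(x, y, edges) {
  lo <- edges[1]; hi <- edges[length(edges)]
  cx <- cut(pmin(pmax(x, lo), hi), edges, include.lowest = TRUE)
  cy <- cut(pmin(pmax(y, lo), hi), edges, include.lowest = TRUE)
  p <- as.vector(table(cx, cy)) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

marginalEntropyOracle <- function(x, edges) {
  lo <- edges[1]; hi <- edges[length(edges)]
  p <- as.vector(table(cut(pmin(pmax(x, lo), hi), edges,
                           include.lowest = TRUE))) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

## a frame with solid axis-aligned colour rectangles; rects is a list of
## list(x0, y0, x1, y1, col) in 0-based pixel coordinates
makeFrame <- function(w, h, rects, background = rep(0.08, 3)) {
  f <- array(rep(background, each = h * w), dim = c(h, w, 3))
  for (rc in rects) {
    rows <- (rc$y0 + 1):(rc$y1 + 1); cols <- (rc$x0 + 1):(rc$x1 + 1)
    for (ch in 1:3) f[rows, cols, ch] <- rc$col[ch]
  }
  f
}

GREEN <- c(0, 0.78, 0.05)
ORANGE <- c(1, 0.55, 0)
BLUE <- c(0.15, 0.25, 1)
greenSpec <- function() colorSpec("dominant", c(90, 150))
orangeSpec <- function() colorSpec("nondominant", c(20, 50))
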