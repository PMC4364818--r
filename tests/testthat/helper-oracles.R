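# Independent oracles used across the suite. These deliberately use naive
# algorithms (queue flood fill, explicit pair enumeration, per-cell edge
# loops) so they share no code path with the package implementation.

# 4-connected component labelling by queue-based flood fill.
oracle_label <- function(cls) {
  ny <- nrow(cls); nx <- ncol(cls)
  lab <- matrix(0L, ny, nx)
  nxt <- 0L
  for (r0 in seq_len(ny)) for (c0 in seq_len(nx)) {
    if (cls[r0, c0] == 0L || lab[r0, c0] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- nxt
    while (length(queue)) {
      cell <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        r <- cell[1] + d[1]; cc <- cell[2] + d[2]
        if (r < 1 || r > ny || cc < 1 || cc > nx) next
        if (cls[r, cc] == cls[cell[1], cell[2]] && lab[r, cc] == 0L) {
          lab[r, cc] <- nxt
          queue[[length(queue) + 1]] <- c(r, cc)
        }
      }
    }
  }
  lab
}

# Per-label boundary-edge counts by explicit per-cell loops.
oracle_perimeter_edges <- function(lab) {
  ny <- nrow(lab); nx <- ncol(lab)
  n <- max(lab)
  per <- numeric(n)
  for (r in seq_len(ny)) for (cc in seq_len(nx)) {
    l <- lab[r, cc]
    if (l == 0L) next
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; ccc <- cc + d[2]
      nb <- if (rr < 1 || rr > ny || ccc < 1 || ccc > nx) 0L
            else lab[rr, ccc]
      if (nb != l) per[l] <- per[l] + 1
    }
  }
  per
}

# Shannon diversity by direct accumulation.
oracle_sdi <- function(p) {
  s <- 0
  for (pi in p) if (pi > 0) s <- s - pi * log(pi)
  s
}

# Kendall tau-b by exhaustive pair enumeration with tie counts.
oracle_tau_b <- function(x, y) {
  n <- length(x); C <- 0; D <- 0; T1 <- 0; T2 <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- sign(x[j] - x[i]); b <- sign(y[j] - y[i])
    if (a == 0 && b == 0) next
    if (a == 0) T1 <- T1 + 1
    else if (b == 0) T2 <- T2 + 1
    else if (a == b) C <- C + 1
    else D <- D + 1
  }
  (C - D) / sqrt((C + D + T1) * (C + D + T2))
}

# Shoelace area of one closed ring.
oracle_shoelace <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1 }
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Random small class mosaic (values 1..k) as a land_grid.
random_mosaic <- function(ny = 20, nx = 20, k = 4, cellsize = 10) {
  cells <- matrix(sample.int(k, ny * nx, replace = TRUE), ny, nx)
  land_grid(cells, paste0("c", seq_len(k)), cellsize)
}

# Rectangle feature aligned to nothing in particular.
rect_feature <- function(x0, y0, x1, y1, props = list(class = "a")) {
  list(props = props,
       rings = list(matrix(c(x0, y0, x1, y0, x1, y1, x0, y1, x0, y0),
                           ncol = 2, byrow = TRUE)))
}

# One-parish uniform zone grid matching a map template.
whole_unit_zones <- function(map, unit_id = "U1") {
  land_grid(matrix(1L, nrow(map$cells), ncol(map$cells)), unit_id,
            map$cellsize, map$origin, map$crs)
}

small_scenario <- function(seed = 1, rows = 2, cols = 4, unit_size_m = 400) {
  hnvf_scenario(rows = rows, cols = cols, unit_size_m = unit_size_m,
                cellsize = 10, seed = seed)
}
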