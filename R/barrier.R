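# Barrier-avoiding distances for the kernel-smoothing interpolator:
# the shortest sequence of straight lines from source to target that does
# not cross any barrier segment, computed over the visibility graph whose
# nodes are the endpoints of all barrier segments plus the two query points.

segments_from_barriers <- function(barriers) {
  segs <- list()
  for (b in barriers) {
    b <- as.matrix(b)
    if (nrow(b) < 2) next
    for (i in seq_len(nrow(b) - 1)) {
      segs[[length(segs) + 1]] <- c(b[i, 1], b[i, 2], b[i + 1, 1], b[i + 1, 2])
    }
  }
  segs
}

cross2 <- function(ox, oy, ax, ay, bx, by) {
  (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
}

# TRUE if open segment pq properly crosses segment s (touching at shared
# endpoints is allowed: paths may bend around barrier endpoints)
seg_blocks <- function(px, py, qx, qy, s, tol = 1e-9) {
  d1 <- cross2(s[1], s[2], s[3], s[4], px, py)
  d2 <- cross2(s[1], s[2], s[3], s[4], qx, qy)
  d3 <- cross2(px, py, qx, qy, s[1], s[2])
  d4 <- cross2(px, py, qx, qy, s[3], s[4])
  scale <- max(abs(c(px, py, qx, qy, s))) + 1
  t2 <- tol * scale^2
  if (((d1 > t2 && d2 < -t2) || (d1 < -t2 && d2 > t2)) &&
      ((d3 > t2 && d4 < -t2) || (d3 < -t2 && d4 > t2))) return(TRUE)
  FALSE
}

visible <- function(px, py, qx, qy, segs) {
  for (s in segs) if (seg_blocks(px, py, qx, qy, s)) return(FALSE)
  TRUE
}

#' Barrier-avoiding shortest-path distances
#'
#' Distance from each source to each destination as the length of the
#' shortest polyline-avoiding path (straight line when unobstructed,
#' otherwise bending around barrier endpoints). `Inf` when no path exists.
#'
#' @param from,to Two-column matrices of point coordinates (meters).
#' @param barriers List of two-column vertex matrices, each an open
#'   polyline acting as an absolute barrier.
#' @return A `nrow(from) x nrow(to)` distance matrix.
#' @export
barrier_distance <- function(from, to, barriers) {
  from <- as_target_matrix(from); to <- as_target_matrix(to)
  segs <- segments_from_barriers(barriers)
  if (length(segs) == 0) {
    return(pair_dist(from[, 1], from[, 2], to[, 1], to[, 2]))
  }
  ends <- unique(do.call(rbind, lapply(segs, function(s) {
    rbind(s[1:2], s[3:4])
  })))
  ne <- nrow(ends)
  # visibility distances among barrier endpoints (shared by every query)
  dE <- matrix(Inf, ne, ne); diag(dE) <- 0
  for (i in seq_len(ne)) for (j in seq_len(ne)) {
    if (i < j && visible(ends[i, 1], ends[i, 2], ends[j, 1], ends[j, 2], segs)) {
      d <- sqrt(sum((ends[i, ] - ends[j, ])^2))
      dE[i, j] <- d; dE[j, i] <- d
    }
  }
  out <- matrix(Inf, nrow(from), nrow(to))
  for (i in seq_len(nrow(from))) {
    p <- from[i, ]
    # Dijkstra from p over {p} + endpoints, then read off each destination
    dp_end <- vapply(seq_len(ne), function(k) {
      if (visible(p[1], p[2], ends[k, 1], ends[k, 2], segs))
        sqrt(sum((p - ends[k, ])^2)) else Inf
    }, 0)
    dist_end <- dijkstra_ends(dE, dp_end)
    for (j in seq_len(nrow(to))) {
      q <- to[j, ]
      direct <- if (visible(p[1], p[2], q[1], q[2], segs))
        sqrt(sum((p - q)^2)) else Inf
      via <- Inf
      for (k in seq_len(ne)) {
        if (is.finite(dist_end[k]) &&
            visible(q[1], q[2], ends[k, 1], ends[k, 2], segs)) {
          via <- min(via, dist_end[k] + sqrt(sum((q - ends[k, ])^2)))
        }
      }
      out[i, j] <- min(direct, via)
    }
  }
  out
}

dijkstra_ends <- function(dE, d0) {
  n <- length(d0)
  dist <- d0
  done <- rep(FALSE, n)
  for (it in seq_len(n)) {
    u <- which(!done & dist == min(dist[!done]))[1]
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    upd <- dist[u] + dE[u, ]
    better <- upd < dist
    dist[better] <- upd[better]
  }
  dist
}
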