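# Shared fixtures, built in code at test time.

# Minimal 4-row scan table: 2 scans x 2 ROIs, one timepoint.
toy_records <- function() {
  data.frame(
    participant = "p1",
    timepoint = "BL",
    day = 1L, session = 1L,
    scan = rep(c("s1", "s2"), each = 2),
    unit_type = "roi",
    unit = rep(c("core", "control"), 2),
    thickness = c(1.8, 2.2, 1.82, 2.21),
    motion = rep(c(2.5, 3.1), each = 2),
    stringsAsFactors = FALSE
  )
}

toy_dataset <- function() cluster_scan_dataset(toy_records())

# Brute-force flood fill over an adjacency list: independent oracle for
# connected components of the induced subgraph.
flood_fill_components <- function(vertices, edges) {
  vs <- sort(unique(vertices))
  adj <- lapply(vs, function(v) {
    nb <- c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1])
    intersect(nb, vs)
  })
  names(adj) <- as.character(vs)
  seen <- setNames(rep(FALSE, length(vs)), as.character(vs))
  comps <- list()
  for (v in vs) {
    if (seen[as.character(v)]) next
    queue <- v
    comp <- integer(0)
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      if (seen[as.character(u)]) next
      seen[as.character(u)] <- TRUE
      comp <- c(comp, u)
      queue <- c(queue, adj[[as.character(u)]])
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps[order(-lengths(comps))]
}

# Random rigid rotation via QR of a Gaussian matrix (det +1).
random_rotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Monte-Carlo oracle for the RMS sphere displacement.
mc_rms_displacement <- function(R, t, radius = 64, center = c(0, 0, 0),
                                n = 4e5) {
  # uniform points in the solid sphere by rejection-free radius scaling
  u <- matrix(stats::rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2)) * radius * stats::runif(n)^(1 / 3)
  p <- sweep(u, 2, center, "+")
  d <- p %*% t(R) - p
  d <- sweep(d, 2, t, "+")
  sqrt(mean(rowSums(d^2)))
}
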