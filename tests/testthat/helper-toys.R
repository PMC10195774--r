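# Shared toy fixtures and independent oracles.

toy_geometry <- function(coords, elements = rep("C", nrow(coords)),
                         carbon_map = integer()) {
  molecular_geometry(elements, coords, carbon_map)
}

diatomic <- function(r0, elements = c("C", "C")) {
  toy_geometry(rbind(c(0, 0, 0), c(r0, 0, 0)), elements)
}

random_rotation <- function() {
  # QR-based uniform random rotation
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

apply_rigid <- function(geom, rot = random_rotation(),
                        shift = stats::rnorm(3, sd = 5)) {
  molecular_geometry(geom$elements,
                     sweep(geom$coords %*% t(rot), 2, -shift),
                     geom$carbon_map)
}

# brute-force breadth-first search on a label edge list (oracle for
# coordination_sphere, independent of igraph)
bfs_sphere <- function(edges, a, b) {
  adj <- list()
  for (i in seq_len(nrow(edges))) {
    adj[[edges[i, 1]]] <- c(adj[[edges[i, 1]]], edges[i, 2])
    adj[[edges[i, 2]]] <- c(adj[[edges[i, 2]]], edges[i, 1])
  }
  if (a == b) return(0L)
  frontier <- a; seen <- a; d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    frontier <- setdiff(unique(unlist(adj[frontier])), seen)
    if (b %in% frontier) return(d)
    seen <- c(seen, frontier)
  }
  NA_integer_
}

# rotate selected atoms of a geometry about the axis through two points
rotate_about_axis <- function(geom, idx, p1, p2, angle_deg) {
  ax <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  xyz <- geom$coords
  for (i in idx) xyz[i, ] <- as.vector(R %*% (xyz[i, ] - p1)) + p1
  molecular_geometry(geom$elements, xyz, geom$carbon_map)
}

# Replace the CH2 hydrogens on `label` by in-plane hydrogens (inside the
# phi reference plane through ref_labels), choosing in-plane directions
# with maximal clearance from the other atoms; makes phi for that side 0.
planarize_ch2 <- function(geom, label, ref_labels) {
  ix <- geom$carbon_map
  ctr <- geom$coords[ix[[label]], ]
  p1 <- geom$coords[ix[[ref_labels[1]]], ]
  p2 <- geom$coords[ix[[ref_labels[2]]], ]
  e1 <- (p1 - ctr) / sqrt(sum((p1 - ctr)^2))
  v <- (p2 - ctr) - sum((p2 - ctr) * e1) * e1
  e2 <- v / sqrt(sum(v^2))
  hyd <- which(geom$elements == "H")
  h <- hyd[sqrt(rowSums(sweep(geom$coords[hyd, , drop = FALSE], 2, ctr)^2)) < 1.3]
  stopifnot(length(h) == 2)
  others <- setdiff(seq_along(geom$elements), h)
  best <- NULL
  for (th in seq(0, 350, by = 10)) {
    d1 <- cos(th * pi / 180) * e1 + sin(th * pi / 180) * e2
    d2 <- cos((th + 115) * pi / 180) * e1 + sin((th + 115) * pi / 180) * e2
    hh <- rbind(ctr + 1.09 * d1, ctr + 1.09 * d2)
    clear <- min(sqrt(rowSums((geom$coords[rep(others, 2), ] -
                               hh[rep(1:2, each = length(others)), ])^2)))
    if (is.null(best) || clear > best$clear) best <- list(clear = clear, hh = hh)
  }
  xyz <- geom$coords
  xyz[h, ] <- best$hh
  molecular_geometry(geom$elements, xyz, geom$carbon_map)
}

all_carbon_pairs <- function() {
  labs <- paste0("C", 1:10)
  t(utils::combn(labs, 2))
}

# independent cross product for normal-vector oracles
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# closed-form error function for fit oracles
erf_local <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
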