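# Independent reference implementations (naive, loop-based) used as oracles.
# These deliberately avoid the code paths they check.

# brute-force rule matcher: score every rule over both tuple orientations
ref_match_rule <- function(rules, types, kind) {
  rules <- Filter(function(r) r$kind == kind && length(r$pattern) == length(types), rules)
  scores <- vapply(rules, function(r) {
    sc <- -1L
    for (tp in list(types, rev(types))) {
      ok <- all(r$pattern == "*" | r$pattern == tp)
      if (ok) sc <- max(sc, sum(r$pattern != "*"))
    }
    sc
  }, 0L)
  if (!length(scores) || max(scores) < 0L) return("nomatch")
  hits <- which(scores == max(scores))
  if (length(hits) > 1L) return("tie")
  rules[[hits]]
}

# brute-force enumeration over all ordered tuples
ref_enum_angles <- function(n, edges) {
  has <- matrix(FALSE, n, n)
  for (r in seq_len(nrow(edges))) {
    has[edges[r, 1], edges[r, 2]] <- TRUE
    has[edges[r, 2], edges[r, 1]] <- TRUE
  }
  out <- NULL
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    if (i != j && j != k && i < k && has[i, j] && has[j, k]) {
      out <- rbind(out, c(i, j, k))
    }
  }
  if (is.null(out)) matrix(integer(), ncol = 3) else out[order(out[,1], out[,2], out[,3]), , drop = FALSE]
}

ref_enum_dihedrals <- function(n, edges) {
  has <- matrix(FALSE, n, n)
  for (r in seq_len(nrow(edges))) {
    has[edges[r, 1], edges[r, 2]] <- TRUE
    has[edges[r, 2], edges[r, 1]] <- TRUE
  }
  out <- NULL
  for (i in 1:n) for (j in 1:n) for (k in 1:n) for (l in 1:n) {
    if (length(unique(c(i, j, k, l))) == 4L && i < l &&
        has[i, j] && has[j, k] && has[k, l]) {
      out <- rbind(out, c(i, j, k, l))
    }
  }
  if (is.null(out)) return(matrix(integer(), ncol = 4))
  out <- unique(out)
  out[order(out[,2], out[,3], out[,1], out[,4]), , drop = FALSE]
}

random_graph <- function(n, p = 0.35) {
  edges <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (stats::runif(1) < p) edges <- rbind(edges, c(i, j))
  }
  if (is.null(edges)) edges <- matrix(c(1L, 2L), ncol = 2)
  structure(list(n = n, edges = edges,
                 provenance = rep("residue_internal", nrow(edges))),
            class = "sbm_bondgraph")
}

# naive O(N^2) cutoff map
ref_contact_map <- function(structure, cutoff, min_sep) {
  at <- structure$atoms
  xyz <- coords(structure)
  out <- NULL
  n <- nrow(at)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    sep_ok <- abs(at$residue[i] - at$residue[j]) >= min_sep ||
      at$chain_idx[i] != at$chain_idx[j]
    if (d <= cutoff && sep_ok) out <- rbind(out, data.frame(i = i, j = j, r0 = d))
  }
  if (is.null(out)) data.frame(i = integer(), j = integer(), r0 = numeric()) else out
}

# naive O(N^3) occlusion scan (point-to-segment distance by minimization)
ref_occlusion <- function(structure, entries, radius) {
  xyz <- coords(structure)
  keep <- logical(nrow(entries))
  for (r in seq_len(nrow(entries))) {
    i <- entries$i[r]; j <- entries$j[r]
    a <- xyz[i, ]; b <- xyz[j, ]
    blocked <- FALSE
    for (k in seq_len(nrow(xyz))) {
      if (k == i || k == j) next
      dseg <- stats::optimize(function(t) sqrt(sum((a + t * (b - a) - xyz[k, ])^2)),
                              c(0, 1))$objective
      dends <- min(sqrt(sum((xyz[k, ] - a)^2)), sqrt(sum((xyz[k, ] - b)^2)))
      if (min(dseg, dends) < radius) { blocked <- TRUE; break }
    }
    keep[r] <- !blocked
  }
  entries[keep, , drop = FALSE]
}

# slow term-by-term energy evaluation (pure R, independent of the C++ path)
ref_energy <- function(top, xyz) {
  e <- list(bonds = 0, angles = 0, dihedrals = 0, contacts = 0, excluded = 0)
  b <- top$bonds
  for (r in seq_len(nrow(b))) {
    d <- sqrt(sum((xyz[b$i[r], ] - xyz[b$j[r], ])^2))
    e$bonds <- e$bonds + 0.5 * b$k[r] * (d - b$r0[r])^2
  }
  a <- top$angles
  for (r in seq_len(nrow(a))) {
    u <- xyz[a$i[r], ] - xyz[a$j[r], ]; v <- xyz[a$k[r], ] - xyz[a$j[r], ]
    th <- acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
    e$angles <- e$angles + 0.5 * a$ktheta[r] * (th - a$theta0[r])^2
  }
  dd <- top$dihedrals
  for (r in seq_len(nrow(dd))) {
    phi <- measure_geometry(xyz, c(dd$i[r], dd$j[r], dd$k[r], dd$l[r]))
    dphi <- phi - dd$phi0[r]
    e$dihedrals <- e$dihedrals +
      dd$kd[r] * ((1 - cos(dphi)) + 0.5 * (1 - cos(3 * dphi)))
  }
  cn <- top$contacts
  for (r in seq_len(nrow(cn))) {
    d <- sqrt(sum((xyz[cn$i[r], ] - xyz[cn$j[r], ])^2))
    e$contacts <- e$contacts +
      contact_potential(d, cn$r0[r], cn$eps[r], cn$form[r],
                        width = if (is.na(cn$width[r])) 0.05 else cn$width[r])
  }
  excl_key <- character()
  if (nrow(top$exclusions)) {
    excl_key <- paste(top$exclusions[, 1], top$exclusions[, 2])
  }
  c12 <- top$atomtypes$c12[match(top$atoms$type, top$atomtypes$type)]
  n <- nrow(xyz)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (paste(i, j) %in% excl_key) next
    d2 <- sum((xyz[i, ] - xyz[j, ])^2)
    e$excluded <- e$excluded + sqrt(c12[i] * c12[j]) / d2^6
  }
  e$total <- e$bonds + e$angles + e$dihedrals + e$contacts + e$excluded
  e
}

# central finite-difference force check; returns max abs deviation
fd_force_dev <- function(top, xyz, h = 1e-6) {
  f <- compute_forces(top, xyz)
  dev <- 0
  for (i in seq_len(nrow(xyz))) for (d in 1:3) {
    xp <- xyz; xp[i, d] <- xp[i, d] + h
    xm <- xyz; xm[i, d] <- xm[i, d] - h
    fd <- -(compute_energy(top, xp)$total - compute_energy(top, xm)$total) / (2 * h)
    dev <- max(dev, abs(f[i, d] - fd))
  }
  list(dev = dev, scale = max(abs(f)))
}
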