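# Deterministic toy structures for tests and examples, plus a synthetic
# 64-residue two-state folder. Geometry is documented in
# inst/extdata/fixture_manifest.tsv.

.fixture_kinds <- c("dimer", "triatomic_bent", "planar_four", "ca_helix",
                    "ca_hairpin", "two_chain")

# cyclic residue-name supply so fixtures exercise several template residues
.fixture_seq <- c("ALA", "GLU", "LEU", "LYS", "VAL", "SER", "ILE", "THR")

.ca_atoms <- function(xyz, resnames, chain = "A", resseq_offset = 0L, serial_offset = 0L) {
  n <- nrow(xyz)
  data.frame(
    serial = serial_offset + seq_len(n),
    name = "CA",
    resname = rep_len(resnames, n),
    resseq = resseq_offset + seq_len(n),
    chain = chain, ins = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE
  )
}

# ideal C-alpha helix: 100 deg/residue twist; radius/rise scaled so the
# consecutive C-alpha distance is exactly 0.38 nm
.helix_trace <- function(n) {
  twist <- 100 * pi / 180
  r0 <- 0.23; d0 <- 0.15
  s <- 0.38 / sqrt((2 * r0 * sin(twist / 2))^2 + d0^2)
  i <- seq_len(n) - 1L
  cbind(x = d0 * s * i, y = r0 * s * cos(twist * i), z = r0 * s * sin(twist * i))
}

# zigzag strand along +x: step 0.334 nm, z alternating +/-0.09 nm
# (consecutive distance sqrt(0.334^2 + 0.18^2) ~ 0.38 nm)
.strand_trace <- function(n, reverse = FALSE) {
  i <- seq_len(n) - 1L
  x <- 0.334 * i
  if (reverse) x <- rev(x)
  cbind(x = x, y = 0, z = 0.09 * (-1)^i)
}

#' Generate a deterministic toy structure
#'
#' Kinds: `dimer` (two bonded beads 0.38 nm apart), `triatomic_bent` (three
#' beads, 100 degree angle), `planar_four` (four beads with a prescribed
#' dihedral, default cis = 0), `ca_helix` (ideal alpha-helix C-alpha trace,
#' 0.38 nm consecutive spacing), `ca_hairpin` (two antiparallel zigzag
#' strands 0.5 nm apart), `two_chain` (two separated helices, chains A/B).
#'
#' @param kind fixture kind.
#' @param n_residues number of residues (ignored for the fixed-size kinds
#'   `dimer`, `triatomic_bent`, `planar_four`).
#' @param seed seed for the optional coordinate jitter.
#' @param jitter Gaussian jitter s.d. in nm (default 0: fully deterministic).
#' @param phi dihedral (rad) for `planar_four` (0 = cis, pi = trans).
#' @return an `sbm_structure`.
#' @export
make_fixture <- function(kind, n_residues = 10L, seed = 1L, jitter = 0, phi = 0) {
  if (!kind %in% .fixture_kinds) {
    user_error("unknown fixture kind '%s' (choose from: %s)", kind,
               paste(.fixture_kinds, collapse = ", "))
  }
  st <- switch(kind,
    dimer = {
      xyz <- rbind(c(0, 0, 0), c(0, 0, 0.38))
      sbm_structure(.ca_atoms(xyz, c("GLY", "ALA")))
    },
    triatomic_bent = {
      a <- 100 * pi / 180
      xyz <- rbind(c(0.38, 0, 0), c(0, 0, 0), 0.38 * c(cos(a), sin(a), 0))
      sbm_structure(.ca_atoms(xyz, c("ALA", "GLY", "ALA")))
    },
    planar_four = {
      th <- 110 * pi / 180
      j <- c(0, 0, 0); k <- c(0.38, 0, 0)
      i <- 0.38 * c(cos(th), sin(th), 0)
      l <- k + 0.38 * c(cos(pi - th), sin(pi - th) * cos(phi), sin(pi - th) * sin(phi))
      sbm_structure(.ca_atoms(rbind(i, j, k, l), rep("ALA", 4)))
    },
    ca_helix = sbm_structure(.ca_atoms(.helix_trace(n_residues), .fixture_seq)),
    ca_hairpin = {
      n1 <- ceiling(n_residues / 2); n2 <- n_residues - n1
      s1 <- .strand_trace(n1)
      s2 <- .strand_trace(n2, reverse = TRUE)
      s2[, 2] <- 0.5
      s2[, 1] <- s2[, 1] + (max(s1[, 1]) - max(s2[, 1]))  # align strand ends
      sbm_structure(.ca_atoms(rbind(s1, s2), .fixture_seq))
    },
    two_chain = {
      h1 <- .helix_trace(n_residues)
      h2 <- .helix_trace(n_residues); h2[, 1] <- h2[, 1] + 2.0
      at <- rbind(.ca_atoms(h1, .fixture_seq, chain = "A"),
                  .ca_atoms(h2, .fixture_seq, chain = "B",
                            resseq_offset = 0L, serial_offset = n_residues))
      sbm_structure(at, chain_breaks = n_residues + 1L)
    }
  )
  if (jitter > 0) {
    set.seed(seed)
    xyz <- coords(st) + matrix(stats::rnorm(3 * nrow(st$atoms), sd = jitter), ncol = 3)
    st$atoms$x <- xyz[, 1]; st$atoms$y <- xyz[, 2]; st$atoms$z <- xyz[, 3]
  }
  st
}

# ---------------------------------------------------------------------------
# Synthetic 64-residue two-state folder ("ci2_synthetic")
#
# A stand-in for a small alpha/beta protein of the chymotrypsin-inhibitor-2
# class, built entirely in code: an alpha-helix packed against a
# four-stranded sheet, 64 residues, with a CA atom and a CB pseudo-sidechain
# centroid 0.25 nm from it (no CB for GLY). It reproduces the size,
# secondary-structure layout and contact density typical of such proteins;
# it is NOT a crystallographic structure.
# ---------------------------------------------------------------------------

# segment layout (residue ranges)
.ci2_layout <- list(
  nterm = 1:4, s1 = 5:11, l1 = 12:12, helix = 13:25, l2 = 26:28,
  s2 = 29:36, l3 = 37:44, s3 = 45:52, l4 = 53:55, s4 = 56:62, cterm = 63:64
)

# 64-residue sequence: GLY enriched in loops, hydrophobics in the core
.ci2_sequence <- c(
  "MET","LYS","THR","GLU",                                       # 1-4
  "TRP","VAL","LEU","ILE","VAL","THR","ALA",                     # s1 5-11
  "GLY",                                                         # l1 12
  "SER","GLU","ALA","LEU","LYS","ALA","ILE","GLU","LEU","ALA",
  "LYS","VAL","GLY",                                             # helix 13-25
  "GLY","PRO","GLY",                                             # l2 26-28
  "ILE","VAL","LEU","PHE","VAL","ALA","THR","SER",               # s2 29-36
  "GLY","GLU","ASP","GLY","LYS","ASN","GLY","ASP",               # l3 37-44
  "VAL","ILE","LEU","VAL","PHE","ALA","THR","GLU",               # s3 45-52
  "GLY","ASN","GLY",                                             # l4 53-55
  "LYS","VAL","LEU","ILE","VAL","ALA","GLU",                     # s4 56-62
  "GLY","ARG"                                                    # 63-64
)

# circular-arc loop between anchors A and B: n interior points with uniform
# arc spacing 0.38 nm, bulging along the component of `out_dir` perpendicular
# to the chord; a small alternating transverse wiggle avoids collinear runs
.arc_loop <- function(A, B, n, out_dir, spacing = 0.38) {
  L <- sqrt(sum((B - A)^2))
  S <- (n + 1) * spacing
  e1 <- (B - A) / L
  u <- out_dir - sum(out_dir * e1) * e1
  if (sqrt(sum(u^2)) < 1e-8) u <- .perp_any(e1) else u <- u / sqrt(sum(u^2))
  M <- (A + B) / 2
  if (S <= L * 1.02) {
    t <- seq_len(n) / (n + 1)
    pts <- outer(1 - t, A) + outer(t, B)
  } else {
    th <- stats::uniroot(function(q) sin(q) / q - L / S, c(1e-6, pi - 1e-6))$root
    R <- S / (2 * th)
    C <- M - R * cos(th) * u
    phi <- -th + 2 * th * seq_len(n) / (n + 1)
    pts <- t(vapply(phi, function(p) C + R * (sin(p) * e1 + cos(p) * u), numeric(3)))
  }
  w <- .perp_any(e1)
  pts + 0.03 * outer((-1)^seq_len(n), w)
}

.perp_any <- function(v) {
  w <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- w - sum(w * v) * v
  u / sqrt(sum(u^2))
}

#' Synthetic 64-residue two-state folder
#'
#' A programmatically generated stand-in for a small alpha/beta protein of
#' the chymotrypsin-inhibitor-2 class: 64 residues, an alpha-helix packed
#' against a four-stranded antiparallel sheet, represented by CA atoms plus
#' a CB pseudo-sidechain centroid 0.25 nm from the CA (omitted for GLY).
#' Deterministic. Secondary-structure spans, strand spacing (0.48 nm),
#' helix-sheet packing distance and sidechain-centroid length were chosen to
#' reproduce the coarse-grained contact density typical of compact
#' single-domain proteins of this size (about 2 residue contacts per
#' residue at a 0.6 nm atomic cutoff with sequence separation >= 4).
#' Intended for coarse-graining and folding experiments where a
#' crystallographic structure is unavailable.
#'
#' @return an `sbm_structure` with 64 residues.
#' @export
make_ci2_synthetic <- function() {
  lay <- .ci2_layout
  ca <- matrix(NA_real_, 64, 3)
  cbdir <- matrix(0, 64, 3)   # unit direction CA -> CB (0 rows: GLY)

  dy <- 0.48                  # sheet strand spacing
  # sheet in the z ~ 0 plane; strand order across the sheet (y):
  #   s2 (y=0), s1 (y=dy), s4 (y=2 dy), s3 (y=3 dy)
  put_strand <- function(idx, y, x0, dir) {
    n <- length(idx)
    tr <- .strand_trace(n)
    if (dir < 0) tr[, 1] <- rev(tr[, 1])
    tr[, 1] <- tr[, 1] + x0
    tr[, 2] <- y
    ca[idx, ] <<- tr
    # sidechain centroids alternate above/below the sheet plane
    updown <- (-1)^(seq_along(idx))
    cbdir[idx, ] <<- cbind(0, 0, updown)
  }
  put_strand(lay$s1, dy,     0.10, +1)   # 5-11  runs +x, ends x=2.10
  put_strand(lay$s2, 0.0,    0.20, +1)   # 29-36 runs +x, starts x=0.20
  put_strand(lay$s3, 3 * dy, 0.10, -1)   # 45-52 runs -x, ends x=0.10
  put_strand(lay$s4, 2 * dy, 0.10, +1)   # 56-62 runs +x, starts x=0.10

  # helix above the sheet over the s1/s4 lane, axis along -x at height 1.0
  h <- .helix_trace(length(lay$helix))
  hx1 <- 2.20
  h[, 1] <- hx1 - h[, 1]               # runs -x from x = 2.20
  h[, 2] <- h[, 2] + 1.5 * dy          # midway between s1 and s4
  h[, 3] <- h[, 3] + 1.00
  ca[lay$helix, ] <- h
  # helix sidechain centroids point radially outward from the axis
  rad <- ca[lay$helix, ] - cbind(ca[lay$helix, 1], 1.5 * dy, 1.00)
  cbdir[lay$helix, ] <- rad / sqrt(rowSums(rad^2))

  up <- c(0, 0, 1)
  body <- c(1.2, 0.72, 0.35)           # rough body centre, loops bulge away
  arc <- function(idx, from, to, out) {
    n <- length(idx)
    A <- ca[from, ]; B <- ca[to, ]
    ca[idx, ] <<- .arc_loop(A, B, n, out)
    cbdir[idx, ] <<- matrix(rep(out / sqrt(sum(out^2)), n), n, 3, byrow = TRUE)
  }
  # loops (anchors are the flanking secondary-structure residues)
  arc(lay$l1, 11, 13, c(0.6, -0.4, 0.4))            # sheet edge up to helix
  arc(lay$l2, 25, 29, c(-0.45, -0.2, 0.15))         # helix down to s2, hugging the -x edge
  arc(lay$l3, 36, 45, c(0.8, 0.1, -0.6))            # long solvent-exposed loop, +x face
  arc(lay$l4, 52, 56, c(-0.8, 0, 0.1))              # s3 down to s4 along the -x edge
  # N-terminal segment packs under the sheet along the s1 lane (as the
  # N-terminus of this fold class does); C-terminus trails off the s4 edge
  A <- ca[5, ] + c(-5 * 0.334, 0, -0.3)
  ca[lay$nterm, ] <- .arc_loop(A, ca[5, ], 4, c(0, 0, -1))
  cbdir[lay$nterm, ] <- matrix(rep(up, 4), 4, 3, byrow = TRUE)
  ct_dir <- c(0.85, -0.3, -0.2); ct_dir <- ct_dir / sqrt(sum(ct_dir^2))
  B <- ca[62, ] + ct_dir * 3 * 0.38
  ca[lay$cterm, ] <- .arc_loop(ca[62, ], B, 2, up)
  cbdir[lay$cterm, ] <- matrix(rep(up, 2), 2, 3, byrow = TRUE)

  cb <- ca + 0.25 * cbdir
  seqs <- .ci2_sequence
  rows <- vector("list", 0)
  serial <- 0L
  for (i in 1:64) {
    serial <- serial + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      serial = serial, name = "CA", resname = seqs[i], resseq = i, chain = "A",
      ins = "", x = ca[i, 1], y = ca[i, 2], z = ca[i, 3], stringsAsFactors = FALSE)
    if (seqs[i] != "GLY") {
      serial <- serial + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        serial = serial, name = "CB", resname = seqs[i], resseq = i, chain = "A",
        ins = "", x = cb[i, 1], y = cb[i, 2], z = cb[i, 3], stringsAsFactors = FALSE)
    }
  }
  sbm_structure(do.call(rbind, rows))
}
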