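# GROMACS-dialect topology serialization. The dialect is self-consistent and
# documented in the file header comments; bit-stable float formatting
# (scientific notation, 9 significant digits) for regression testing.
#
# Conventions (also written into every file header):
#  * harmonic stiffness k with V = (k/2) dx^2, so k equals the model's
#    eps_b / eps_theta exactly (no factor-of-2 rescaling);
#  * angles are degrees in the file, radians internally (k stays per rad^2);
#  * each dihedral is two periodic lines V = k [1 + cos(n phi - phase)] with
#    phase_n = n*phi0 + 180 deg, multiplicities 1 (full strength) and 3
#    (half strength);
#  * [pairs] function type 1 encodes the 12-10 contact as C10, C12 with
#    V = C12/r^12 - C10/r^10, C12 = 5 eps r0^12, C10 = 6 eps r0^10
#    (minimum at r0, depth -eps); type 5 is the Gaussian well
#    (eps, r0, width); type 6 the harmonic spring (r0, k);
#  * excluded volume enters through the atomtype c12 = eps_NC * sigma_NC^12;
#  * [exclusions] lists every [pairs] entry; bonded exclusions are implied
#    by nrexcl.
# Stock GROMACS reads [pairs] as 6-12; these files are meant for the bundled
# simulator or an SBM-enhanced build.

.fmt_f <- function(x) sprintf("%.8e", x)

#' Write a topology file
#'
#' Serializes an `sbm_topology` to the package's GROMACS-dialect `.top`
#' format (see the header comments the file carries for the exact
#' conventions). Indices are 1-based in the file.
#'
#' @param topology an `sbm_topology`.
#' @param path output file.
#' @export
write_top <- function(topology, path) {
  t <- topology
  L <- c(
    sprintf("; structure-based model topology, generator sbmr %s, template %s",
            t$provenance$generator, t$provenance$template),
    "; conventions: V_bond=(k/2)(r-r0)^2 with k=eps_b exactly; angles deg in file, k per rad^2;",
    "; dihedrals: two periodic lines V=k(1+cos(n*phi-phase)), phase_n = n*phi0+180deg, n=1 full, n=3 half strength;",
    "; pairs ftype 1: C10 C12 of V=C12/r^12-C10/r^10 (12-10 well); ftype 5: gaussian eps r0 width; ftype 6: harmonic r0 k;",
    sprintf("; settings sigma_NC=%s epsilon_NC=%s", .fmt_f(t$settings$sigma_NC),
            .fmt_f(t$settings$epsilon_NC)),
    "", "[ defaults ]", "; nbfunc comb-rule gen-pairs", "  1 1 no",
    "", "[ atomtypes ]", "; name mass charge ptype c6 c12 ; sigma eps_nc")
  for (k in seq_len(nrow(t$atomtypes))) {
    a <- t$atomtypes[k, ]
    L <- c(L, sprintf(" %s 1.0 0.0 A 0.0 %s ; %s %s",
                      a$type, .fmt_f(a$c12), .fmt_f(a$sigma), .fmt_f(a$eps_nc)))
  }
  L <- c(L, "", "[ moleculetype ]", "; name nrexcl",
         sprintf(" Macromolecule %d", t$settings$exclusion_depth),
         "", "[ atoms ]", "; nr type resnr residue atom cgnr charge mass")
  at <- t$atoms
  L <- c(L, sprintf(" %d %s %d %s %s %d %s %s",
                    seq_len(nrow(at)), at$type, at$residue, at$resname, at$name,
                    seq_len(nrow(at)), .fmt_f(at$charge), .fmt_f(at$mass)))

  L <- c(L, "", "[ bonds ]", "; i j ftype r0(nm) k")
  if (nrow(t$bonds)) {
    L <- c(L, sprintf(" %d %d 1 %s %s", t$bonds$i, t$bonds$j,
                      .fmt_f(t$bonds$r0), .fmt_f(t$bonds$k)))
  }
  L <- c(L, "", "[ angles ]", "; i j k ftype theta0(deg) k")
  if (nrow(t$angles)) {
    L <- c(L, sprintf(" %d %d %d 1 %s %s", t$angles$i, t$angles$j, t$angles$k,
                      .fmt_f(t$angles$theta0 * 180 / pi), .fmt_f(t$angles$ktheta)))
  }
  L <- c(L, "", "[ dihedrals ]", "; i j k l ftype phase(deg) k mult")
  if (nrow(t$dihedrals)) {
    d <- t$dihedrals
    phase1 <- d$phi0 * 180 / pi + 180
    phase3 <- 3 * d$phi0 * 180 / pi + 180
    lines1 <- sprintf(" %d %d %d %d 1 %s %s 1", d$i, d$j, d$k, d$l,
                      .fmt_f(phase1), .fmt_f(d$kd))
    lines3 <- sprintf(" %d %d %d %d 1 %s %s 3", d$i, d$j, d$k, d$l,
                      .fmt_f(phase3), .fmt_f(d$kd / 2))
    L <- c(L, as.vector(rbind(lines1, lines3)))
  }
  L <- c(L, "", "[ pairs ]", "; i j ftype params (see header)")
  if (nrow(t$contacts)) {
    cn <- t$contacts
    for (k in seq_len(nrow(cn))) {
      L <- c(L, switch(cn$form[k],
        lj_12_10 = sprintf(" %d %d 1 %s %s", cn$i[k], cn$j[k],
                           .fmt_f(6 * cn$eps[k] * cn$r0[k]^10),
                           .fmt_f(5 * cn$eps[k] * cn$r0[k]^12)),
        gaussian = sprintf(" %d %d 5 %s %s %s", cn$i[k], cn$j[k],
                           .fmt_f(cn$eps[k]), .fmt_f(cn$r0[k]), .fmt_f(cn$width[k])),
        harmonic = sprintf(" %d %d 6 %s %s", cn$i[k], cn$j[k],
                           .fmt_f(cn$r0[k]), .fmt_f(cn$eps[k]))))
    }
  }
  L <- c(L, "", "[ exclusions ]", "; i j (one line per pairs entry)")
  if (nrow(t$contacts)) {
    L <- c(L, sprintf(" %d %d", t$contacts$i, t$contacts$j))
  }
  L <- c(L, "", "[ system ]", " structure-based model", "", "[ molecules ]",
         " Macromolecule 1")
  writeLines(L, path)
  invisible(path)
}

#' Read a topology file
#'
#' Parses a `.top` file in the dialect written by [write_top()] back into an
#' `sbm_topology`. Consecutive dihedral lines with multiplicities 1 and 3 on
#' the same quadruple are merged into a single dihedral record. The
#' reconstructed topology has no coordinates (`coords` is NULL); supply them
#' from the matching GRO file.
#'
#' @param path topology file.
#' @return an `sbm_topology`.
#' @export
read_top <- function(path) {
  if (!file.exists(path)) user_error("topology file not found: %s", path)
  raw <- readLines(path, warn = FALSE)

  settings_line <- grep("^; settings ", raw, value = TRUE)
  sigma_NC <- epsilon_NC <- NA_real_
  if (length(settings_line)) {
    sigma_NC <- as.numeric(sub(".*sigma_NC=([^ ]+).*", "\\1", settings_line[1]))
    epsilon_NC <- as.numeric(sub(".*epsilon_NC=([^ ]+).*", "\\1", settings_line[1]))
  }
  template <- sub(".*template ", "", grep("generator", raw, value = TRUE)[1])
  if (is.na(template)) template <- "unknown"

  # split into sections; strip comments except the atomtype sigma/eps carrier
  sec <- NULL
  sections <- list()
  for (ln in raw) {
    s <- trimws(ln)
    if (grepl("^\\[", s)) {
      sec <- gsub("[][ ]", "", s)
      sections[[sec]] <- character()
      next
    }
    if (is.null(sec)) next
    if (sec != "atomtypes") s <- trimws(sub(";.*", "", s))
    if (s == "" || startsWith(s, ";")) next
    sections[[sec]] <- c(sections[[sec]], s)
  }
  need <- c("atoms", "moleculetype")
  for (s in need) if (is.null(sections[[s]])) user_error("missing [%s] section", s)

  toks <- function(lines) {
    if (is.null(lines)) return(list())
    lapply(strsplit(lines, "\\s+"), function(x) x[x != ""])
  }

  mt <- toks(sections$moleculetype)[[1]]
  nrexcl <- as.integer(mt[2])

  atl <- toks(sections$atoms)
  atoms <- data.frame(
    type = vapply(atl, `[`, "", 2),
    residue = as.integer(vapply(atl, `[`, "", 3)),
    resname = vapply(atl, `[`, "", 4),
    name = vapply(atl, `[`, "", 5),
    charge = as.numeric(vapply(atl, `[`, "", 7)),
    mass = as.numeric(vapply(atl, `[`, "", 8)),
    stringsAsFactors = FALSE
  )
  atoms$resseq <- atoms$residue
  atoms$chain <- "A"
  n <- nrow(atoms)
  chk_idx <- function(i, what) {
    if (any(i < 1L | i > n)) {
      user_error("%s references atom index outside 1..%d (1-based contract)", what, n)
    }
    i
  }

  att <- toks(sections$atomtypes)
  atomtypes <- data.frame(
    type = vapply(att, `[`, "", 1),
    c12 = as.numeric(vapply(att, `[`, "", 6)),
    sigma = as.numeric(vapply(att, function(x) if (length(x) >= 9) x[8] else NA_character_, "")),
    eps_nc = as.numeric(vapply(att, function(x) if (length(x) >= 9) x[9] else NA_character_, "")),
    stringsAsFactors = FALSE
  )

  bl <- toks(sections$bonds)
  bonds <- if (length(bl)) {
    m <- do.call(rbind, lapply(bl, as.numeric))
    if (any(m[, 3] != 1)) user_error("unknown bond function type %g", m[m[, 3] != 1, 3][1])
    data.frame(i = chk_idx(as.integer(m[, 1]), "bonds"),
               j = chk_idx(as.integer(m[, 2]), "bonds"),
               r0 = m[, 4], k = m[, 5])
  } else data.frame(i = integer(), j = integer(), r0 = numeric(), k = numeric())

  al <- toks(sections$angles)
  angles <- if (length(al)) {
    m <- do.call(rbind, lapply(al, as.numeric))
    if (any(m[, 4] != 1)) user_error("unknown angle function type %g", m[m[, 4] != 1, 4][1])
    data.frame(i = chk_idx(as.integer(m[, 1]), "angles"),
               j = chk_idx(as.integer(m[, 2]), "angles"),
               k = chk_idx(as.integer(m[, 3]), "angles"),
               theta0 = m[, 5] * pi / 180, ktheta = m[, 6])
  } else data.frame(i = integer(), j = integer(), k = integer(),
                    theta0 = numeric(), ktheta = numeric())

  dl <- toks(sections$dihedrals)
  dihedrals <- data.frame(i = integer(), j = integer(), k = integer(), l = integer(),
                          phi0 = numeric(), kd = numeric())
  if (length(dl)) {
    m <- do.call(rbind, lapply(dl, as.numeric))
    if (any(m[, 5] != 1)) user_error("unknown dihedral function type %g", m[m[, 5] != 1, 5][1])
    r <- 1L
    while (r <= nrow(m)) {
      if (m[r, 8] != 1) user_error("unpaired dihedral line with multiplicity %d", m[r, 8])
      if (r + 1L > nrow(m) || m[r + 1L, 8] != 3 || any(m[r + 1L, 1:4] != m[r, 1:4])) {
        user_error("dihedral at line %d lacks its multiplicity-3 partner line", r)
      }
      phi0 <- (m[r, 6] - 180) * pi / 180
      phi0 <- phi0 - 2 * pi * floor((phi0 + pi) / (2 * pi))
      if (phi0 <= -pi) phi0 <- phi0 + 2 * pi
      dihedrals <- rbind(dihedrals, data.frame(
        i = as.integer(m[r, 1]), j = as.integer(m[r, 2]),
        k = as.integer(m[r, 3]), l = as.integer(m[r, 4]),
        phi0 = phi0, kd = m[r, 7]))
      r <- r + 2L
    }
    chk_idx(c(dihedrals$i, dihedrals$j, dihedrals$k, dihedrals$l), "dihedrals")
  }

  pl <- toks(sections$pairs)
  contacts <- data.frame(i = integer(), j = integer(), r0 = numeric(),
                         eps = numeric(), form = character(), width = numeric())
  for (x in pl) {
    v <- as.numeric(x)
    i <- chk_idx(as.integer(v[1]), "pairs"); j <- chk_idx(as.integer(v[2]), "pairs")
    rec <- switch(as.character(v[3]),
      "1" = {
        C10 <- v[4]; C12 <- v[5]
        r0 <- sqrt(6 * C12 / (5 * C10))
        data.frame(i = i, j = j, r0 = r0, eps = C10 / (6 * r0^10),
                   form = "lj_12_10", width = NA_real_)
      },
      "5" = data.frame(i = i, j = j, r0 = v[5], eps = v[4], form = "gaussian", width = v[6]),
      "6" = data.frame(i = i, j = j, r0 = v[4], eps = v[5], form = "harmonic", width = NA_real_),
      user_error("unknown pairs function type %g", v[3]))
    contacts <- rbind(contacts, rec)
  }

  graph <- structure(list(n = n, edges = as.matrix(bonds[, c("i", "j")]),
                          provenance = rep("residue_internal", nrow(bonds))),
                     class = "sbm_bondgraph")
  excl <- .bonded_within(graph, nrexcl)
  el <- toks(sections$exclusions)
  if (length(el)) {
    m <- do.call(rbind, lapply(el, function(x) sort(as.integer(x[1:2]))))
    excl <- rbind(excl, m)
  }
  if (nrow(excl)) {
    excl <- unique(excl[order(excl[, 1], excl[, 2]), , drop = FALSE])
  }
  colnames(excl) <- c("i", "j")

  structure(list(
    atoms = atoms[, c("name", "resname", "resseq", "chain", "residue", "type",
                      "mass", "charge")],
    coords = NULL, bonds = bonds, angles = angles, dihedrals = dihedrals,
    contacts = contacts, exclusions = excl, atomtypes = atomtypes,
    settings = list(sigma_NC = sigma_NC, epsilon_NC = epsilon_NC,
                    exclusion_depth = nrexcl),
    provenance = list(template = template, generator = .sbmr_version())
  ), class = "sbm_topology")
}
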