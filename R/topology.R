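# Covalent bond graph construction, angle/dihedral enumeration, native
# geometry measurement, coarse-graining and topology assembly.

#' Build the covalent bond graph
#'
#' Per-residue internal bonds come from the template residue definitions;
#' consecutive residues within a chain are joined through the template's
#' connect atoms (previous residue's `out` atom to the next residue's `in`
#' atom); user extra bonds are appended. No inter-chain bonds are created
#' except through `extra_bonds`.
#'
#' @param structure an `sbm_structure` with names normalized against the
#'   templates (see [adjust_names()]).
#' @param template_set a parsed template set.
#' @return an object of class `sbm_bondgraph`: list with `n` (atom count),
#'   `edges` (two-column index matrix, i < j) and `provenance` (character:
#'   "residue_internal", "inter_residue", "user_extra").
#' @export
build_bond_graph <- function(structure, template_set) {
  at <- structure$atoms
  n <- nrow(at)
  res_ids <- unique(at$residue)
  edges <- matrix(integer(), ncol = 2)
  prov <- character()

  res_rows <- split(seq_len(n), at$residue)
  add_edge <- function(i, j, p) {
    edges <<- rbind(edges, c(min(i, j), max(i, j)))
    prov <<- c(prov, p)
  }

  for (r in res_ids) {
    rows <- res_rows[[as.character(r)]]
    resname <- at$resname[rows[1]]
    tmpl <- template_set$residues[[resname]]
    if (is.null(tmpl)) {
      user_error("residue '%s' (residue %d) has no template entry", resname, r)
    }
    bonds <- tmpl$bonds
    for (k in seq_len(nrow(bonds))) {
      ia <- rows[match(bonds[k, 1], at$name[rows])]
      ib <- rows[match(bonds[k, 2], at$name[rows])]
      if (is.na(ia) || is.na(ib)) {
        missing <- bonds[k, c(is.na(ia), is.na(ib))][1]
        user_error("residue %s %d: template bond atom '%s' missing from structure",
                   resname, at$resseq[rows[1]], missing)
      }
      add_edge(ia, ib, "residue_internal")
    }
  }

  # inter-residue junctions: consecutive residues in the same chain
  for (k in seq_along(res_ids)[-1]) {
    r_prev <- res_ids[k - 1]; r_next <- res_ids[k]
    rows_p <- res_rows[[as.character(r_prev)]]
    rows_n <- res_rows[[as.character(r_next)]]
    if (at$chain_idx[rows_p[1]] != at$chain_idx[rows_n[1]]) next
    tmpl_p <- template_set$residues[[at$resname[rows_p[1]]]]
    tmpl_n <- template_set$residues[[at$resname[rows_n[1]]]]
    if (is.na(tmpl_p$connect_out) && is.na(tmpl_n$connect_in)) {
      next   # bond-free template (e.g. elastic network): no covalent chain
    }
    if (is.na(tmpl_p$connect_out) || is.na(tmpl_n$connect_in)) {
      user_error("residue %s or %s lacks connect atoms but is chained",
                 tmpl_p$name, tmpl_n$name)
    }
    ia <- rows_p[match(tmpl_p$connect_out, at$name[rows_p])]
    ib <- rows_n[match(tmpl_n$connect_in, at$name[rows_n])]
    if (is.na(ia)) user_error("residue %s %d: connect atom '%s' missing at junction",
                              tmpl_p$name, at$resseq[rows_p[1]], tmpl_p$connect_out)
    if (is.na(ib)) user_error("residue %s %d: connect atom '%s' missing at junction",
                              tmpl_n$name, at$resseq[rows_n[1]], tmpl_n$connect_in)
    add_edge(ia, ib, "inter_residue")
  }

  eb <- structure$extra_bonds
  for (k in seq_len(nrow(eb))) add_edge(eb[k, 1], eb[k, 2], "user_extra")

  if (nrow(edges)) {
    key <- paste(edges[, 1], edges[, 2])
    dup <- duplicated(key)
    edges <- edges[!dup, , drop = FALSE]
    prov <- prov[!dup]
  }
  structure(list(n = n, edges = edges, provenance = prov), class = "sbm_bondgraph")
}

.adjacency_list <- function(graph) {
  adj <- vector("list", graph$n)
  for (k in seq_len(nrow(graph$edges))) {
    i <- graph$edges[k, 1]; j <- graph$edges[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  lapply(adj, function(v) sort(unique(v)))
}

#' Enumerate bond angles from a bond graph
#'
#' Every simple path i-j-k (i and k both bonded to j, i != k), listed once
#' with i < k.
#'
#' @param graph an `sbm_bondgraph`.
#' @return integer matrix with columns i, j, k.
#' @export
enumerate_angles <- function(graph) {
  adj <- .adjacency_list(graph)
  out <- list()
  for (j in seq_len(graph$n)) {
    nb <- adj[[j]]
    if (length(nb) < 2L) next
    cmb <- utils::combn(nb, 2)
    out[[length(out) + 1L]] <- cbind(cmb[1, ], j, cmb[2, ])
  }
  if (!length(out)) return(matrix(integer(), ncol = 3, dimnames = list(NULL, c("i", "j", "k"))))
  m <- do.call(rbind, out)
  colnames(m) <- c("i", "j", "k")
  m[order(m[, 2], m[, 1], m[, 3]), , drop = FALSE]
}

#' Enumerate proper dihedrals from a bond graph
#'
#' Every simple path i-j-k-l around each central bond (j, k), in canonical
#' orientation (i < l). Three-cycles (i == l) are skipped.
#'
#' @param graph an `sbm_bondgraph`.
#' @return integer matrix with columns i, j, k, l.
#' @export
enumerate_dihedrals <- function(graph) {
  adj <- .adjacency_list(graph)
  out <- list()
  for (e in seq_len(nrow(graph$edges))) {
    j <- graph$edges[e, 1]; k <- graph$edges[e, 2]
    for (i in setdiff(adj[[j]], k)) {
      for (l in setdiff(adj[[k]], j)) {
        if (i == l) next
        q <- if (i < l) c(i, j, k, l) else c(l, k, j, i)
        out[[length(out) + 1L]] <- q
      }
    }
  }
  if (!length(out)) return(matrix(integer(), ncol = 4, dimnames = list(NULL, c("i", "j", "k", "l"))))
  m <- unique(do.call(rbind, out))
  colnames(m) <- c("i", "j", "k", "l")
  m[order(m[, 2], m[, 3], m[, 1], m[, 4]), , drop = FALSE]
}

#' Measure native geometry
#'
#' Two indices: distance (nm). Three: interior angle (rad) via the arccos of
#' the normalized dot product. Four: proper dihedral (rad) by the atan2
#' convention, right-handed about the j -> k axis, in (-pi, pi].
#'
#' @param structure an `sbm_structure` (or an n x 3 coordinate matrix).
#' @param indices 2, 3 or 4 atom indices.
#' @return the measured value.
#' @export
measure_geometry <- function(structure, indices) {
  xyz <- if (is.matrix(structure)) structure else coords(structure)
  p <- xyz[indices, , drop = FALSE]
  switch(as.character(length(indices)),
    "2" = sqrt(sum((p[2, ] - p[1, ])^2)),
    "3" = {
      v1 <- p[1, ] - p[2, ]; v2 <- p[3, ] - p[2, ]
      n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
      if (n1 < 1e-12 || n2 < 1e-12) stop("degenerate geometry: coincident points in angle", call. = FALSE)
      acos(pmin(1, pmax(-1, sum(v1 * v2) / (n1 * n2))))
    },
    "4" = {
      b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
      c1 <- .cross3(b1, b2); c2 <- .cross3(b2, b3)
      nb2 <- sqrt(sum(b2^2))
      if (sum(c1^2) < 1e-20 || sum(c2^2) < 1e-20) {
        stop("degenerate geometry: collinear atoms in dihedral", call. = FALSE)
      }
      phi <- atan2(sum(.cross3(c1, c2) * b2) / nb2, sum(c1 * c2))
      if (phi <= -pi) phi <- phi + 2 * pi
      phi
    },
    stop("indices must have length 2, 3 or 4", call. = FALSE)
  )
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Coarse-grain a structure using a template
#'
#' Keeps, for each residue, the single atom declared by the coarse-grained
#' template (the template set's `cg_partner` if it has one, otherwise the set
#' itself, whose residue definitions must then declare exactly one atom). The
#' kept atom retains its position; chain breaks are preserved. The mapping
#' from coarse-grained bead to original atom index is attached as attribute
#' `cg_mapping`, and the original per-atom residue index as `residue_of_atom`.
#'
#' @param structure an `sbm_structure`.
#' @param template_set a parsed template set.
#' @return the coarse-grained `sbm_structure` (one bead per residue).
#' @export
coarse_grain <- function(structure, template_set) {
  cg <- template_set$cg_partner
  if (is.null(cg)) cg <- template_set
  at <- structure$atoms
  res_rows <- split(seq_len(nrow(at)), at$residue)
  keep <- integer(length(res_rows))
  names_out <- character(length(res_rows))
  for (k in seq_along(res_rows)) {
    rows <- res_rows[[k]]
    resname <- at$resname[rows[1]]
    tmpl <- cg$residues[[resname]]
    if (is.null(tmpl)) {
      user_error("coarse-graining: residue '%s' missing from the CG template", resname)
    }
    if (nrow(tmpl$atoms) != 1L) {
      user_error("CG template residue '%s' must declare exactly one atom (has %d)",
                 resname, nrow(tmpl$atoms))
    }
    kept_name <- tmpl$atoms$name[1]
    idx <- rows[match(kept_name, at$name[rows])]
    if (is.na(idx)) {
      user_error("residue %s %d lacks its designated coarse-graining atom '%s'",
                 resname, at$resseq[rows[1]], kept_name)
    }
    keep[k] <- idx
    names_out[k] <- kept_name
  }
  new_at <- at[keep, , drop = FALSE]
  new_at$name <- names_out
  new_at$serial <- seq_along(keep)
  new_at$residue <- NULL; new_at$chain_idx <- NULL
  # chain breaks: first bead of every chain after the first
  chain_of_bead <- at$chain_idx[keep]
  breaks <- which(diff(chain_of_bead) != 0) + 1L
  out <- sbm_structure(new_at, chain_breaks = breaks)
  attr(out, "cg_mapping") <- keep
  attr(out, "residue_of_atom") <- at$residue
  out
}

# all pairs within `depth` bonds of each other (for nonbonded exclusions)
.bonded_within <- function(graph, depth) {
  adj <- .adjacency_list(graph)
  out <- list()
  for (s in seq_len(graph$n)) {
    dist <- rep(NA_integer_, graph$n)
    dist[s] <- 0L
    frontier <- s
    for (d in seq_len(depth)) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[is.na(dist[nxt])]
      if (!length(nxt)) break
      dist[nxt] <- d
      frontier <- nxt
    }
    reached <- which(!is.na(dist) & seq_len(graph$n) > s)
    if (length(reached)) out[[length(out) + 1L]] <- cbind(s, reached)
  }
  if (!length(out)) return(matrix(integer(), ncol = 2))
  do.call(rbind, out)
}

#' Assemble a fully parameterized topology
#'
#' Builds the bond graph, enumerates angles and dihedrals, measures native
#' geometry, and parameterizes every term through template rule matching and
#' placeholder resolution. Native contacts are parameterized through the pair
#' rules with the contact list's native distances. Nonbonded exclusions are
#' all pairs within `exclusion_depth` bonds plus all contact pairs. Contacts
#' that coincide with a covalent bond are dropped (with a warning when the
#' contact list was user-supplied).
#'
#' @param structure an `sbm_structure`, names normalized.
#' @param template_set a parsed template set.
#' @param contacts an `sbm_contacts` whose indices refer to `structure`
#'   (or NULL for no native contacts).
#' @return an object of class `sbm_topology`.
#' @export
assemble_topology <- function(structure, template_set, contacts = NULL) {
  at <- structure$atoms
  xyz <- coords(structure)
  n <- nrow(at)
  graph <- build_bond_graph(structure, template_set)

  btype <- character(n); nbtype <- character(n); ptype <- character(n)
  mass <- numeric(n); charge <- numeric(n)
  for (i in seq_len(n)) {
    ta <- .template_atom(template_set, at$resname[i], at$name[i])
    if (is.null(ta)) {
      user_error("atom %s/%s %d not declared by template '%s' (run adjust_names first?)",
                 at$name[i], at$resname[i], at$resseq[i], template_set$name)
    }
    btype[i] <- ta$btype; nbtype[i] <- ta$nbtype; ptype[i] <- ta$ptype
    mass[i] <- ta$mass; charge[i] <- ta$charge
  }

  brules <- template_set$bonded_rules
  param_tuples <- function(tuples, kind) {
    m <- nrow(tuples)
    if (m == 0L) return(NULL)
    vals <- numeric(m); eps <- numeric(m); func <- character(m)
    for (r in seq_len(m)) {
      idx <- tuples[r, ]
      rule <- match_rule(brules, btype[idx], kind = kind)
      measured <- measure_geometry(xyz, idx)
      p <- resolve_placeholders(rule, if (any(rule$placeholder)) measured else NULL)
      vals[r] <- p[1]; eps[r] <- p[2]; func[r] <- rule$func
    }
    list(vals = vals, eps = eps, func = func)
  }

  bonds_m <- graph$edges
  bp <- param_tuples(bonds_m, "bond")
  bonds <- if (is.null(bp)) {
    data.frame(i = integer(), j = integer(), r0 = numeric(), k = numeric())
  } else {
    data.frame(i = bonds_m[, 1], j = bonds_m[, 2], r0 = bp$vals, k = bp$eps)
  }

  ang_m <- enumerate_angles(graph)
  ap <- param_tuples(ang_m, "angle")
  angles <- if (is.null(ap)) {
    data.frame(i = integer(), j = integer(), k = integer(),
               theta0 = numeric(), ktheta = numeric())
  } else {
    data.frame(i = ang_m[, 1], j = ang_m[, 2], k = ang_m[, 3],
               theta0 = ap$vals, ktheta = ap$eps)
  }

  dih_m <- enumerate_dihedrals(graph)
  dp <- param_tuples(dih_m, "dihedral")
  dihedrals <- if (is.null(dp)) {
    data.frame(i = integer(), j = integer(), k = integer(), l = integer(),
               phi0 = numeric(), kd = numeric())
  } else {
    data.frame(i = dih_m[, 1], j = dih_m[, 2], k = dih_m[, 3], l = dih_m[, 4],
               phi0 = dp$vals, kd = dp$eps)
  }

  # native contacts via pair rules
  con <- data.frame(i = integer(), j = integer(), r0 = numeric(),
                    eps = numeric(), form = character(), width = numeric())
  if (!is.null(contacts) && nrow(contacts$entries)) {
    e <- contacts$entries
    bond_key <- paste(bonds$i, bonds$j)
    is_bond <- paste(e$i, e$j) %in% bond_key
    if (any(is_bond)) {
      # auto-generated maps routinely include bonded neighbours; only a
      # user-supplied list deserves a warning about them
      if (identical(contacts$provenance, "user_supplied")) {
        warning(sprintf("%d contacts coincide with covalent bonds and were dropped",
                        sum(is_bond)))
      }
      e <- e[!is_bond, , drop = FALSE]
    }
    m <- nrow(e)
    if (m) {
      r0 <- e$r0; eps <- numeric(m); form <- character(m); width <- rep(NA_real_, m)
      for (r in seq_len(m)) {
        rule <- match_rule(template_set$pair_rules, ptype[c(e$i[r], e$j[r])], kind = "pair")
        p <- resolve_placeholders(rule, if (any(rule$placeholder)) e$r0[r] else NULL)
        decl <- template_set$functions[[rule$func]]
        form[r] <- switch(decl$form,
                          contact_12_10 = "lj_12_10",
                          contact_gaussian = "gaussian",
                          contact_harmonic = "harmonic",
                          user_error("pair rule %s has non-contact form %s", rule$func, decl$form))
        r0[r] <- p[1]; eps[r] <- p[2]
        if (decl$form == "contact_gaussian") width[r] <- p[3]
      }
      con <- data.frame(i = e$i, j = e$j, r0 = r0, eps = eps, form = form, width = width)
    }
  }

  # per-nonbonded-type excluded volume
  types <- unique(nbtype)
  atomtypes <- data.frame(type = types, sigma = NA_real_, eps_nc = NA_real_)
  for (k in seq_along(types)) {
    p <- tryCatch({
      rule <- match_rule(template_set$nonbond_rules, types[k], kind = "nonbond")
      resolve_placeholders(rule)
    }, error = function(e) c(template_set$settings$sigma_NC, template_set$settings$epsilon_NC))
    atomtypes$sigma[k] <- p[1]; atomtypes$eps_nc[k] <- p[2]
  }
  atomtypes$c12 <- atomtypes$eps_nc * atomtypes$sigma^12

  depth <- template_set$settings$exclusion_depth
  excl <- .bonded_within(graph, depth)
  if (nrow(con)) excl <- rbind(excl, cbind(con$i, con$j))
  if (nrow(excl)) excl <- unique(excl[order(excl[, 1], excl[, 2]), , drop = FALSE])
  colnames(excl) <- c("i", "j")

  atoms <- data.frame(
    name = at$name, resname = at$resname, resseq = at$resseq, chain = at$chain,
    residue = at$residue, type = nbtype, mass = mass, charge = charge,
    stringsAsFactors = FALSE
  )
  structure(list(
    atoms = atoms, coords = xyz, bonds = bonds, angles = angles,
    dihedrals = dihedrals, contacts = con, exclusions = excl,
    atomtypes = atomtypes,
    settings = template_set$settings,
    provenance = list(template = template_set$name, generator = .sbmr_version())
  ), class = "sbm_topology")
}

.sbmr_version <- function() {
  as.character(utils::packageVersion("sbmr"))
}

#' @export
print.sbm_topology <- function(x, ...) {
  cat(sprintf(paste0("SBM topology (template '%s'): %d atoms, %d bonds, %d angles, ",
                     "%d dihedrals, %d contacts, %d exclusions\n"),
              x$provenance$template, nrow(x$atoms), nrow(x$bonds), nrow(x$angles),
              nrow(x$dihedrals), nrow(x$contacts), nrow(x$exclusions)))
  invisible(x)
}

#' Rescale stabilizing energies (contact/dihedral balance)
#'
#' Rescales contact strengths and dihedral strengths so that the total
#' stabilizing energy equals `total` (default: the number of atoms, in
#' reduced units) and the ratio of summed contact energy to summed dihedral
#' energy equals `ratio` (default 2). A convention used by all-atom
#' structure-based models; the constants here are provisional defaults and
#' should be checked against any model one needs compatibility with.
#'
#' @param topology an `sbm_topology`.
#' @param ratio target (sum of contact strengths) / (sum of dihedral strengths).
#' @param total target total stabilizing energy in reduced units.
#' @return the rescaled topology.
#' @export
normalize_energies <- function(topology, ratio = 2, total = nrow(topology$atoms)) {
  sc <- sum(topology$contacts$eps)
  sd <- sum(topology$dihedrals$kd)
  if (sc == 0 || sd == 0) {
    warning("no contacts or no dihedrals: energies left unchanged")
    return(topology)
  }
  eps_c <- total * ratio / (1 + ratio) / nrow(topology$contacts)
  eps_d <- total * 1 / (1 + ratio) / nrow(topology$dihedrals)
  topology$contacts$eps <- rep(eps_c, nrow(topology$contacts))
  topology$dihedrals$kd <- rep(eps_d, nrow(topology$dihedrals))
  topology
}
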