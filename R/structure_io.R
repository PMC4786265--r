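# PDB reading, name normalization, GRO writing and toy-structure fixtures.
# Coordinates are stored in nm throughout (PDB Angstrom values are converted
# once, at parse time).

user_error <- function(msg, ...) {
  stop(structure(class = c("sbm_user_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = NULL)))
}

#' Construct a structure object
#'
#' @param atoms data.frame with columns `serial`, `name`, `resname`,
#'   `resseq`, `chain`, `ins` (insertion code, "" if none) and coordinates
#'   `x`, `y`, `z` in nm.
#' @param chain_breaks integer indices of atoms that start a new physical
#'   chain (the first atom of the first chain is implicit).
#' @param extra_bonds two-column integer matrix of user-supplied bonds
#'   (atom indices), used for irregular chains.
#' @return an object of class `sbm_structure`. A `residue` column (sequential
#'   residue index over the whole structure) and a `chain_idx` column are
#'   derived and attached.
#' @export
sbm_structure <- function(atoms, chain_breaks = integer(), extra_bonds = NULL) {
  stopifnot(is.data.frame(atoms))
  need <- c("serial", "name", "resname", "resseq", "chain", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  if (!"ins" %in% names(atoms)) atoms$ins <- ""
  if (nrow(atoms) > 0 && !all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in structure", call. = FALSE)
  }
  chain_breaks <- sort(unique(as.integer(chain_breaks)))
  chain_breaks <- chain_breaks[chain_breaks > 1L & chain_breaks <= nrow(atoms)]

  # chain index per atom
  chain_idx <- integer(nrow(atoms))
  if (nrow(atoms)) {
    chain_idx <- cumsum(seq_len(nrow(atoms)) %in% c(1L, chain_breaks))
  }
  atoms$chain_idx <- chain_idx
  # sequential residue index: new residue whenever (chain_idx,resseq,ins,resname) changes
  if (nrow(atoms)) {
    key <- paste(chain_idx, atoms$resseq, atoms$ins, atoms$resname, sep = "\r")
    atoms$residue <- cumsum(c(TRUE, key[-1] != key[-length(key)]))
  } else {
    atoms$residue <- integer()
  }
  key2 <- paste(atoms$chain, atoms$resseq, atoms$ins, atoms$name, sep = "\r")
  if (anyDuplicated(key2)) {
    dup <- atoms[duplicated(key2), ][1, ]
    stop(sprintf("duplicate atom (chain %s, residue %d%s, atom %s)",
                 dup$chain, dup$resseq, dup$ins, dup$name), call. = FALSE)
  }
  if (!is.null(extra_bonds)) {
    extra_bonds <- matrix(as.integer(extra_bonds), ncol = 2)
    if (nrow(extra_bonds) && (min(extra_bonds) < 1L || max(extra_bonds) > nrow(atoms))) {
      stop("extra_bonds reference atoms outside the structure", call. = FALSE)
    }
  } else {
    extra_bonds <- matrix(integer(), ncol = 2)
  }
  structure(list(atoms = atoms, chain_breaks = chain_breaks,
                 extra_bonds = extra_bonds),
            class = "sbm_structure")
}

#' @export
print.sbm_structure <- function(x, ...) {
  n_ch <- if (nrow(x$atoms)) max(x$atoms$chain_idx) else 0L
  n_res <- if (nrow(x$atoms)) max(x$atoms$residue) else 0L
  cat(sprintf("Structure: %d atoms, %d residues, %d chain(s)\n",
              nrow(x$atoms), n_res, n_ch))
  invisible(x)
}

#' Coordinates of a structure as an n x 3 matrix (nm)
#' @param structure an `sbm_structure`.
#' @export
coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

# Chain-break threshold (nm): a residue-numbering gap starts a new chain only
# if the two residues are also farther apart than a bondable distance.
.BONDABLE_NM <- 0.3

#' Read a PDB file
#'
#' Fixed-column PDB v3.3 ATOM/HETATM records. Coordinates are converted from
#' Angstrom to nm (x 0.1). A new physical chain starts at a TER record, at a
#' chain-identifier change, or at a residue-numbering gap whose flanking
#' residues are farther apart than 0.3 nm (a bondable distance). Alternate
#' locations other than blank or 'A' are dropped with a warning; models after
#' the first are ignored with a warning. Insertion codes are kept and treated
#' as distinct residues.
#'
#' @param path PDB file.
#' @return an `sbm_structure`.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) user_error("PDB file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  in_model1 <- TRUE
  model_seen <- 0L
  keep <- logical(length(lines))
  ter_after <- integer()   # number of kept atoms before each TER
  n_kept <- 0L
  skipped_models <- FALSE
  for (i in seq_along(lines)) {
    r <- rec[i]
    if (startsWith(r, "MODEL")) {
      model_seen <- model_seen + 1L
      in_model1 <- model_seen <= 1L
      if (!in_model1) skipped_models <- TRUE
    } else if (startsWith(r, "ENDMDL")) {
      in_model1 <- FALSE
    } else if (startsWith(r, "TER")) {
      if (in_model1) ter_after <- c(ter_after, n_kept)
    } else if (r == "ATOM  " || r == "HETATM") {
      if (in_model1) { keep[i] <- TRUE; n_kept <- n_kept + 1L }
    }
  }
  if (skipped_models) warning("multi-model PDB: only MODEL 1 was read")
  lines <- lines[keep]
  if (length(lines) == 0L) user_error("no ATOM/HETATM records in %s", path)

  fld <- function(a, b) trimws(substr(lines, a, b))
  numfld <- function(a, b, what) {
    v <- suppressWarnings(as.numeric(fld(a, b)))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      user_error("malformed PDB record (non-numeric %s) at atom line %d: '%s'",
                 what, bad, lines[bad])
    }
    v
  }
  atoms <- data.frame(
    serial  = suppressWarnings(as.integer(fld(7, 11))),
    name    = fld(13, 16),
    altloc  = substr(lines, 17, 17),
    resname = fld(18, 20),
    chain   = substr(lines, 22, 22),
    resseq  = suppressWarnings(as.integer(fld(23, 26))),
    ins     = trimws(substr(lines, 27, 27)),
    x       = numfld(31, 38, "x") * 0.1,
    y       = numfld(39, 46, "y") * 0.1,
    z       = numfld(47, 54, "z") * 0.1,
    stringsAsFactors = FALSE
  )
  if (anyNA(atoms$resseq)) user_error("malformed PDB record: non-numeric residue number")
  if (anyNA(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))

  alt_drop <- !(atoms$altloc %in% c(" ", "", "A"))
  if (any(alt_drop)) {
    warning(sprintf("dropped %d alternate-location atoms (altloc not blank/'A')",
                    sum(alt_drop)))
    drop_rank <- cumsum(!alt_drop)
    ter_after <- drop_rank[pmax(ter_after, 1L)] * (ter_after > 0L)
    atoms <- atoms[!alt_drop, , drop = FALSE]
  }
  atoms$altloc <- NULL
  n <- nrow(atoms)

  breaks <- ter_after[ter_after > 0L & ter_after < n] + 1L
  # chain-id change
  if (n > 1L) {
    chg <- which(atoms$chain[-1] != atoms$chain[-n]) + 1L
    breaks <- c(breaks, chg)
    # residue-numbering gap + spatial separation
    same_chain <- atoms$chain[-1] == atoms$chain[-n]
    new_res <- atoms$resseq[-1] != atoms$resseq[-n] | atoms$ins[-1] != atoms$ins[-n]
    gap <- abs(atoms$resseq[-1] - atoms$resseq[-n]) > 1L
    cand <- which(same_chain & new_res & gap) + 1L
    for (i in cand) {
      prev_res <- atoms$resseq == atoms$resseq[i - 1L] & atoms$chain == atoms$chain[i - 1L] &
        atoms$ins == atoms$ins[i - 1L]
      next_res <- atoms$resseq == atoms$resseq[i] & atoms$chain == atoms$chain[i] &
        atoms$ins == atoms$ins[i]
      d2 <- .min_dist2(as.matrix(atoms[prev_res, c("x", "y", "z")]),
                       as.matrix(atoms[next_res, c("x", "y", "z")]))
      if (d2 > .BONDABLE_NM^2) breaks <- c(breaks, i)
    }
  }
  sbm_structure(atoms, chain_breaks = breaks)
}

.min_dist2 <- function(A, B) {
  min(vapply(seq_len(nrow(A)), function(i) {
    min(colSums((t(B) - A[i, ])^2))
  }, 0))
}

#' Write a minimal fixed-column PDB file
#'
#' Coordinates are converted nm -> Angstrom. TER records are written at chain
#' breaks. Intended for fixtures and round-trip testing.
#'
#' @param structure an `sbm_structure`.
#' @param path output file.
#' @export
write_pdb <- function(structure, path) {
  at <- structure$atoms
  if (nrow(at) == 0L) user_error("refusing to write an empty structure")
  out <- character()
  breaks <- structure$chain_breaks
  for (i in seq_len(nrow(at))) {
    if (i %in% breaks) out <- c(out, "TER")
    nm <- at$name[i]
    # PDB atom-name column convention: names < 4 chars start in column 14
    nm_fmt <- if (nchar(nm) >= 4) substr(nm, 1, 4) else sprintf(" %-3s", nm)
    out <- c(out, sprintf("ATOM  %5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f",
                          at$serial[i] %% 100000, nm_fmt, at$resname[i],
                          at$chain[i], at$resseq[i] %% 10000,
                          ifelse(at$ins[i] == "", " ", at$ins[i]),
                          at$x[i] * 10, at$y[i] * 10, at$z[i] * 10))
  }
  out <- c(out, "TER", "END")
  writeLines(out, path)
  invisible(path)
}

#' Normalize residue/atom naming against a template set
#'
#' Applies an alias table (PDB naming variants -> template vocabulary), then
#' checks every atom against the template residue definitions. Hydrogens not
#' declared by the template are silently dropped; other undeclared atoms are
#' dropped with a warning that lists them. A residue name with no template
#' entry and no alias is an error.
#'
#' @param structure an `sbm_structure`.
#' @param template_set a parsed template set.
#' @param aliases data.frame with columns `kind` ("atom" or "residue"),
#'   `from`, `to`; defaults to [default_alias_table()].
#' @param drop_unmatched drop atoms the template does not declare (default
#'   TRUE). Set FALSE for single-template coarse-graining pipelines, where
#'   undeclared atoms still feed the atomic contact map.
#' @return the normalized `sbm_structure`.
#' @export
adjust_names <- function(structure, template_set, aliases = default_alias_table(),
                         drop_unmatched = TRUE) {
  at <- structure$atoms
  res_alias <- aliases[aliases$kind == "residue", , drop = FALSE]
  m <- match(at$resname, res_alias$from)
  at$resname[!is.na(m)] <- res_alias$to[m[!is.na(m)]]

  unknown <- setdiff(unique(at$resname), names(template_set$residues))
  if (length(unknown)) {
    first <- at[at$resname == unknown[1], ][1, ]
    user_error("residue '%s' (chain %s, residue %d) has no template entry and no alias",
               unknown[1], first$chain, first$resseq)
  }

  atom_alias <- aliases[aliases$kind == "atom", , drop = FALSE]
  keep <- rep(TRUE, nrow(at))
  unmatched <- character()
  for (i in seq_len(nrow(at))) {
    decl <- template_set$residues[[at$resname[i]]]$atoms$name
    nm <- at$name[i]
    if (nm %in% decl) next
    j <- match(nm, atom_alias$from)
    if (!is.na(j) && atom_alias$to[j] %in% decl) {
      at$name[i] <- atom_alias$to[j]
      next
    }
    if (grepl("^[0-9]*H", nm)) {      # hydrogen not declared by template
      keep[i] <- FALSE
      next
    }
    if (drop_unmatched) {
      keep[i] <- FALSE
      unmatched <- c(unmatched, sprintf("%s/%s%d/%s", at$resname[i], at$chain[i],
                                        at$resseq[i], nm))
    }
  }
  if (length(unmatched)) {
    warning(sprintf("dropped %d atoms with no template match: %s",
                    length(unmatched), paste(unique(unmatched), collapse = ", ")))
  }
  # remap chain breaks to kept-atom indexing
  kept_rank <- cumsum(keep)
  breaks <- structure$chain_breaks
  breaks <- unique(kept_rank[pmax(breaks - 1L, 1L)] + 1L)
  sbm_structure(at[keep, , drop = FALSE], chain_breaks = breaks,
                extra_bonds = if (nrow(structure$extra_bonds)) {
                  eb <- matrix(kept_rank[structure$extra_bonds], ncol = 2)
                  eb[keep[structure$extra_bonds[, 1]] & keep[structure$extra_bonds[, 2]], ,
                     drop = FALSE]
                } else NULL)
}

#' Default residue/atom alias table
#'
#' Common PDB naming variants mapped to the bundled template vocabulary:
#' terminal oxygen variants (OT1 -> O, OT2 -> OXT), O1/O2 variants and
#' histidine protonation-state names (HSD/HSE/HSP/HID/HIE/HIP -> HIS).
#'
#' @return data.frame with columns `kind`, `from`, `to`.
#' @export
default_alias_table <- function() {
  data.frame(
    kind = c("atom", "atom", "atom", "atom",
             "residue", "residue", "residue", "residue", "residue", "residue"),
    from = c("OT1", "OT2", "O1", "O2",
             "HSD", "HSE", "HSP", "HID", "HIE", "HIP"),
    to   = c("O", "OXT", "O", "OXT",
             "HIS", "HIS", "HIS", "HIS", "HIS", "HIS"),
    stringsAsFactors = FALSE
  )
}

#' Write coordinates in GRO format
#'
#' Fixed-format GRO file, positions in nm with 3 decimals. The box line is the
#' axis-aligned bounding box of the coordinates plus `padding` on every side.
#' Atom serials wrap modulo 100000 per the GRO convention.
#'
#' @param structure an `sbm_structure`.
#' @param path output file.
#' @param padding box padding in nm (default 1.0).
#' @param title first line of the file.
#' @export
write_gro <- function(structure, path, padding = 1.0, title = "generated by sbmr") {
  at <- structure$atoms
  if (nrow(at) == 0L) user_error("refusing to write an empty structure to GRO")
  lines <- c(title, sprintf("%5d", nrow(at)))
  lines <- c(lines, sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                            at$residue %% 100000, substr(at$resname, 1, 5),
                            substr(at$name, 1, 5), seq_len(nrow(at)) %% 100000,
                            at$x, at$y, at$z))
  ext <- apply(as.matrix(at[, c("x", "y", "z")]), 2, function(v) diff(range(v)))
  box <- ext + 2 * padding
  lines <- c(lines, sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GRO coordinate file
#'
#' Parses a single-frame fixed-format GRO file back into an `sbm_structure`
#' (chain information is not stored in GRO; a single chain is assumed).
#'
#' @param path GRO file.
#' @return an `sbm_structure`.
#' @export
read_gro <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) user_error("truncated GRO file: %s", path)
  n <- as.integer(trimws(lines[2]))
  if (is.na(n) || length(lines) < 2L + n + 1L) user_error("truncated GRO file: %s", path)
  body <- lines[3:(2 + n)]
  atoms <- data.frame(
    serial  = as.integer(trimws(substr(body, 16, 20))),
    name    = trimws(substr(body, 11, 15)),
    resname = trimws(substr(body, 6, 10)),
    resseq  = as.integer(trimws(substr(body, 1, 5))),
    chain   = "A",
    ins     = "",
    x       = as.numeric(substr(body, 21, 28)),
    y       = as.numeric(substr(body, 29, 36)),
    z       = as.numeric(substr(body, 37, 44)),
    stringsAsFactors = FALSE
  )
  sbm_structure(atoms)
}

#' Read a user extra-bond file
#'
#' Plain text, one bond per line:
#' `chain_i resseq_i atomname_i chain_j resseq_j atomname_j`.
#' Lines starting with `#` are comments.
#'
#' @param path file path.
#' @param structure the structure the bonds refer to.
#' @return two-column integer matrix of atom indices.
#' @export
read_extra_bonds <- function(path, structure) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[lines != ""]
  at <- structure$atoms
  out <- matrix(integer(), ncol = 2)
  for (ln in lines) {
    f <- strsplit(ln, "\\s+")[[1]]
    if (length(f) != 6L) user_error("extra-bond line needs 6 fields: '%s'", ln)
    idx <- vapply(c(1, 4), function(k) {
      i <- which(at$chain == f[k] & at$resseq == as.integer(f[k + 1]) & at$name == f[k + 2])
      if (length(i) != 1L) user_error("extra bond: atom %s/%s/%s not found (or ambiguous)",
                                      f[k], f[k + 1], f[k + 2])
      i
    }, 0L)
    out <- rbind(out, sort(idx))
  }
  out
}
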