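# Native contact maps: distance-cutoff generation, optional line-of-sight
# occlusion filtering, mapping onto coarse-grained beads, and the
# four-column contact file format.

#' Construct a contact list
#'
#' @param entries data.frame with integer columns `i`, `j` (atom indices,
#'   i < j enforced by normalization) and `r0` (native distance, nm).
#' @param level "atomic" or "residue".
#' @param provenance "cutoff", "occlusion_filtered" or "user_supplied".
#' @return an object of class `sbm_contacts`.
#' @export
sbm_contacts <- function(entries, level = c("atomic", "residue"),
                         provenance = c("cutoff", "occlusion_filtered", "user_supplied")) {
  level <- match.arg(level)
  provenance <- match.arg(provenance)
  if (nrow(entries)) {
    swap <- entries$i > entries$j
    tmp <- entries$i[swap]; entries$i[swap] <- entries$j[swap]; entries$j[swap] <- tmp
    if (any(entries$i == entries$j)) stop("contact joins an atom to itself", call. = FALSE)
    key <- paste(entries$i, entries$j)
    if (anyDuplicated(key)) stop("duplicate contact pair", call. = FALSE)
    entries <- entries[order(entries$i, entries$j), , drop = FALSE]
    rownames(entries) <- NULL
    if (any(entries$r0 <= 0)) stop("contact with non-positive native distance", call. = FALSE)
  }
  structure(list(entries = entries, level = level, provenance = provenance),
            class = "sbm_contacts")
}

#' @export
print.sbm_contacts <- function(x, ...) {
  cat(sprintf("Contact list: %d %s-level contacts (%s)\n",
              nrow(x$entries), x$level, x$provenance))
  invisible(x)
}

.empty_contact_entries <- function() {
  data.frame(i = integer(), j = integer(), r0 = numeric())
}

#' Distance-cutoff native contact map
#'
#' All atom pairs closer than `cutoff` whose residue-sequence separation is at
#' least `min_seq_separation`; pairs on different chains are always eligible.
#' Residue separation is counted on the sequential residue index (insertion
#' codes count as separate residues).
#'
#' @param structure an `sbm_structure`.
#' @param cutoff distance cutoff in nm (default 0.6, the conventional 6
#'   Angstrom atomic cutoff).
#' @param min_seq_separation minimum residue separation within a chain
#'   (default 1: exclude only same-residue pairs).
#' @return an `sbm_contacts` at atomic level.
#' @export
cutoff_contact_map <- function(structure, cutoff = 0.6, min_seq_separation = 1L) {
  stopifnot(cutoff > 0)
  at <- structure$atoms
  n <- nrow(at)
  if (n < 2L) return(sbm_contacts(.empty_contact_entries(), "atomic", "cutoff"))
  xyz <- coords(structure)
  d <- as.matrix(stats::dist(xyz))
  sep <- abs(outer(at$residue, at$residue, "-"))
  diff_chain <- outer(at$chain_idx, at$chain_idx, "!=")
  eligible <- (sep >= min_seq_separation) | diff_chain
  hit <- which(upper.tri(d) & d <= cutoff & eligible, arr.ind = TRUE)
  entries <- data.frame(i = hit[, 1], j = hit[, 2],
                        r0 = d[hit])
  sbm_contacts(entries, "atomic", "cutoff")
}

#' Line-of-sight occlusion filter for a contact map
#'
#' Removes a contact (i, j) if any third atom's centre lies within
#' `screening_radius` of the i-j segment (point-to-segment distance): the
#' line of sight between the two atoms is occluded. A coarse stand-in for
#' shadow-style contact screening; it is not a reproduction of that
#' algorithm's atom-radius light-casting geometry.
#'
#' @param structure the structure the contacts were measured on.
#' @param contact_list an atomic-level `sbm_contacts`.
#' @param screening_radius occluder radius in nm (default 0.1).
#' @return filtered `sbm_contacts` with provenance `occlusion_filtered`.
#' @export
occlusion_filter <- function(structure, contact_list, screening_radius = 0.1) {
  stopifnot(inherits(contact_list, "sbm_contacts"))
  if (contact_list$level != "atomic") {
    stop("occlusion filter operates on atomic-level contact lists", call. = FALSE)
  }
  xyz <- coords(structure)
  e <- contact_list$entries
  keep <- vapply(seq_len(nrow(e)), function(k) {
    i <- e$i[k]; j <- e$j[k]
    others <- setdiff(seq_len(nrow(xyz)), c(i, j))
    if (!length(others)) return(TRUE)
    dmin <- .point_segment_dist(xyz[others, , drop = FALSE], xyz[i, ], xyz[j, ])
    all(dmin >= screening_radius)
  }, logical(1))
  sbm_contacts(e[keep, , drop = FALSE], "atomic", "occlusion_filtered")
}

# distance from each row of P to segment a-b
.point_segment_dist <- function(P, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt(colSums((t(P) - a)^2)))
  t <- pmin(1, pmax(0, (sweep(P, 2, a) %*% ab) / len2))
  proj <- outer(as.numeric(t), ab) + matrix(a, nrow(P), 3, byrow = TRUE)
  sqrt(rowSums((P - proj)^2))
}

#' Map atomic contacts onto coarse-grained beads
#'
#' A residue pair (I, J) becomes a coarse-grained contact iff at least one
#' atomic contact joins residues I and J and their separation along the chain
#' is at least `min_seq_separation`. The native distance is re-measured
#' between the coarse-grained beads. Same-residue pairs are dropped.
#'
#' @param contact_list an atomic-level `sbm_contacts` measured on the
#'   original structure.
#' @param residue_mapping for each atom of the original structure, its
#'   sequential residue index (e.g. `structure$atoms$residue`).
#' @param cg_structure the coarse-grained structure (one bead per residue, in
#'   residue order), as produced by [coarse_grain()].
#' @param min_seq_separation minimum residue separation within a chain
#'   (default 4; inter-chain pairs always eligible).
#' @return an `sbm_contacts` at residue level.
#' @export
map_contacts_to_cg <- function(contact_list, residue_mapping, cg_structure,
                               min_seq_separation = 4L) {
  stopifnot(inherits(contact_list, "sbm_contacts"))
  e <- contact_list$entries
  if (nrow(e) == 0L) {
    return(sbm_contacts(.empty_contact_entries(), "residue", contact_list$provenance))
  }
  ri <- residue_mapping[e$i]
  rj <- residue_mapping[e$j]
  swap <- ri > rj
  tmp <- ri[swap]; ri[swap] <- rj[swap]; rj[swap] <- tmp
  keep <- ri != rj
  pairs <- unique(data.frame(i = ri[keep], j = rj[keep]))

  cg_at <- cg_structure$atoms
  if (nrow(cg_at) < max(c(pairs$i, pairs$j, 0))) {
    stop("cg_structure has fewer beads than the residue mapping implies", call. = FALSE)
  }
  same_chain <- cg_at$chain_idx[pairs$i] == cg_at$chain_idx[pairs$j]
  sep_ok <- abs(pairs$j - pairs$i) >= min_seq_separation | !same_chain
  pairs <- pairs[sep_ok, , drop = FALSE]
  xyz <- coords(cg_structure)
  pairs$r0 <- sqrt(rowSums((xyz[pairs$i, , drop = FALSE] - xyz[pairs$j, , drop = FALSE])^2))
  sbm_contacts(pairs, "residue", contact_list$provenance)
}

#' Read a contact file
#'
#' Whitespace-delimited four-column text: `chain_i atom_i chain_j atom_j`,
#' atom indices 1-based within their chain; `#` starts a comment. Native
#' distances are measured on `structure` at read time.
#'
#' @param path contact file.
#' @param structure the structure the indices refer to.
#' @param level level tag for the resulting list (default "atomic").
#' @return an `sbm_contacts` with provenance `user_supplied`.
#' @export
read_contact_file <- function(path, structure, level = "atomic") {
  if (!file.exists(path)) user_error("contact file not found: %s", path)
  raw <- readLines(path, warn = FALSE)
  at <- structure$atoms
  chains <- split(seq_len(nrow(at)), at$chain_idx)
  ent <- .empty_contact_entries()
  xyz <- coords(structure)
  for (ln_no in seq_along(raw)) {
    ln <- trimws(sub("#.*", "", raw[ln_no]))
    if (ln == "") next
    f <- strsplit(ln, "\\s+")[[1]]
    if (length(f) != 4L) user_error("line %d: expected 4 fields, got %d", ln_no, length(f))
    ci <- suppressWarnings(as.integer(f[1])); ai <- suppressWarnings(as.integer(f[2]))
    cj <- suppressWarnings(as.integer(f[3])); aj <- suppressWarnings(as.integer(f[4]))
    if (anyNA(c(ci, ai, cj, aj))) user_error("line %d: non-integer field", ln_no)
    for (cc in c(ci, cj)) if (cc < 1L || cc > length(chains))
      user_error("line %d: chain index %d out of range", ln_no, cc)
    if (ai < 1L || ai > length(chains[[ci]]))
      user_error("line %d: atom index %d beyond chain %d length %d",
                 ln_no, ai, ci, length(chains[[ci]]))
    if (aj < 1L || aj > length(chains[[cj]]))
      user_error("line %d: atom index %d beyond chain %d length %d",
                 ln_no, aj, cj, length(chains[[cj]]))
    gi <- chains[[ci]][ai]; gj <- chains[[cj]][aj]
    if (gi == gj) user_error("line %d: contact joins an atom to itself", ln_no)
    ent <- rbind(ent, data.frame(i = gi, j = gj,
                                 r0 = sqrt(sum((xyz[gi, ] - xyz[gj, ])^2))))
  }
  key <- paste(pmin(ent$i, ent$j), pmax(ent$i, ent$j))
  if (anyDuplicated(key)) {
    user_error("duplicate contact pair at line %d", which(duplicated(key))[1])
  }
  sbm_contacts(ent, level = level, provenance = "user_supplied")
}

#' Write a contact file
#'
#' Inverse of [read_contact_file()]: four columns, chain index and 1-based
#' atom index within the chain.
#'
#' @param contact_list an `sbm_contacts`.
#' @param structure the structure the indices refer to.
#' @param path output file.
#' @export
write_contact_file <- function(contact_list, structure, path) {
  at <- structure$atoms
  # position of each atom within its chain
  within <- stats::ave(seq_len(nrow(at)), at$chain_idx, FUN = seq_along)
  e <- contact_list$entries
  lines <- c("# chain_i atom_i chain_j atom_j",
             sprintf("%d %d %d %d", at$chain_idx[e$i], within[e$i],
                     at$chain_idx[e$j], within[e$j]))
  writeLines(lines, path)
  invisible(path)
}
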