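# Shared fixture builders for the test suite.

# deterministic generic (non-collinear) positions for an all-atom toy peptide
make_tripeptide <- function(resnames = c("ALA", "GLY", "SER")) {
  atoms_of <- list(
    ALA = c("N", "CA", "C", "O", "CB"),
    GLY = c("N", "CA", "C", "O"),
    SER = c("N", "CA", "C", "O", "CB", "OG")
  )
  set.seed(424242)
  rows <- list(); serial <- 0L
  pos <- c(0, 0, 0)
  for (k in seq_along(resnames)) {
    rn <- resnames[k]
    for (nm in atoms_of[[rn]]) {
      serial <- serial + 1L
      pos <- pos + c(0.12, 0, 0) + stats::rnorm(3, sd = 0.05)
      rows[[serial]] <- data.frame(serial = serial, name = nm, resname = rn,
                                   resseq = k, chain = "A", ins = "",
                                   x = pos[1], y = pos[2], z = pos[3],
                                   stringsAsFactors = FALSE)
    }
  }
  sbm_structure(do.call(rbind, rows))
}

# expected covalent edges of the tripeptide above (atom names per residue)
tripeptide_expected_bonds <- function() {
  list(
    c("1N", "1CA"), c("1CA", "1C"), c("1C", "1O"), c("1CA", "1CB"),
    c("1C", "2N"),
    c("2N", "2CA"), c("2CA", "2C"), c("2C", "2O"),
    c("2C", "3N"),
    c("3N", "3CA"), c("3CA", "3C"), c("3C", "3O"), c("3CA", "3CB"),
    c("3CB", "3OG")
  )
}

# write a minimal single-residue CA template set into dir; returns dir.
# `bond_extra` injects an intra-residue bond (for invalid-template tests).
write_mini_template <- function(dir, bond_extra = NULL, dup_rule = FALSE,
                                cg_partner = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  res <- c('<residues>', '  <residue name="ALA" class="amino">',
           '    <atom name="CA" bType="CA" nbType="CA" pType="CA"/>')
  if (!is.null(bond_extra)) {
    res <- c(res, sprintf('    <bond a="%s" b="%s"/>', bond_extra[1], bond_extra[2]))
  }
  res <- c(res, '    <connect out="CA" in="CA"/>', '  </residue>', '</residues>')
  writeLines(res, file.path(dir, "residues.xml"))
  writeLines(c('<settings>', '  <functions>',
               '    <function name="bond_harmonic" form="harmonic_bond" arity="2"/>',
               '    <function name="angle_harmonic" form="harmonic_angle" arity="2"/>',
               '    <function name="dihedral_sbm" form="periodic_dihedral_1_3" arity="2"/>',
               '    <function name="contact_12_10" form="contact_12_10" arity="2"/>',
               '    <function name="excluded_12" form="excluded_12" arity="2"/>',
               '  </functions>',
               '  <nonbonded_settings sigma_NC="0.4" epsilon_NC="1.0" exclusion_depth="3"/>',
               '</settings>'), file.path(dir, "settings.xml"))
  bonded <- c('<bonded>',
              '  <bond func="bond_harmonic(?,20000)">',
              '    <bType>*</bType>', '    <bType>*</bType>', '  </bond>')
  if (dup_rule) {
    bonded <- c(bonded,
                '  <bond func="bond_harmonic(?,99)">',
                '    <bType>*</bType>', '    <bType>*</bType>', '  </bond>')
  }
  bonded <- c(bonded,
              '  <angle func="angle_harmonic(?,40)">',
              '    <bType>*</bType>', '    <bType>*</bType>', '    <bType>*</bType>',
              '  </angle>',
              '  <dihedral func="dihedral_sbm(?,1)">',
              '    <bType>*</bType>', '    <bType>*</bType>', '    <bType>*</bType>',
              '    <bType>*</bType>', '  </dihedral>',
              '</bonded>')
  writeLines(bonded, file.path(dir, "bonded.xml"))
  writeLines(c('<nonbonded>',
               '  <nonbond func="excluded_12(0.4,1.0)">',
               '    <nbType>*</nbType>', '  </nonbond>',
               '  <pair func="contact_12_10(?,1.0)">',
               '    <pType>*</pType>', '    <pType>*</pType>', '  </pair>',
               '</nonbonded>'), file.path(dir, "nonbonded.xml"))
  if (cg_partner) {
    write_mini_template(file.path(dir, "cg"))
  }
  dir
}

# construct synthetic rule lists for the matcher oracle
make_rules <- function(patterns, kind = "bond") {
  lapply(seq_along(patterns), function(k) {
    list(kind = kind, pattern = patterns[[k]], func = paste0("f", k),
         params = c(NA_real_, 1), placeholder = c(TRUE, FALSE))
  })
}

# bare topology builder for simulator-level tests
bare_topology <- function(n, coords, bonds = NULL, angles = NULL, dihedrals = NULL,
                          contacts = NULL, exclusions = NULL, sigma = 0.4, eps_nc = 1) {
  empty <- list(
    bonds = data.frame(i = integer(), j = integer(), r0 = numeric(), k = numeric()),
    angles = data.frame(i = integer(), j = integer(), k = integer(),
                        theta0 = numeric(), ktheta = numeric()),
    dihedrals = data.frame(i = integer(), j = integer(), k = integer(), l = integer(),
                           phi0 = numeric(), kd = numeric()),
    contacts = data.frame(i = integer(), j = integer(), r0 = numeric(),
                          eps = numeric(), form = character(), width = numeric())
  )
  structure(list(
    atoms = data.frame(name = "CA", resname = "ALA", resseq = seq_len(n), chain = "A",
                       residue = seq_len(n), type = "CA", mass = 1, charge = 0),
    coords = coords,
    bonds = if (is.null(bonds)) empty$bonds else bonds,
    angles = if (is.null(angles)) empty$angles else angles,
    dihedrals = if (is.null(dihedrals)) empty$dihedrals else dihedrals,
    contacts = if (is.null(contacts)) empty$contacts else contacts,
    exclusions = if (is.null(exclusions)) matrix(integer(), ncol = 2) else exclusions,
    atomtypes = data.frame(type = "CA", sigma = sigma, eps_nc = eps_nc,
                           c12 = eps_nc * sigma^12),
    settings = list(sigma_NC = sigma, epsilon_NC = eps_nc, exclusion_depth = 3L),
    provenance = list(template = "test", generator = "test")
  ), class = "sbm_topology")
}

all_pairs <- function(n) t(utils::combn(n, 2))

# the standard coarse-grained folding testbed
ci2_ca_topology <- function() ci2_synthetic_model()
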