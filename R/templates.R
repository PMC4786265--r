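# Forcefield template sets: four XML documents per directory
#   residues.xml   - atoms, types, charges/masses and covalent bonds per residue
#   settings.xml   - declared functional forms + system-wide nonbonded settings
#   bonded.xml     - typed rules for bonds/angles/dihedrals
#   nonbonded.xml  - typed rules for excluded volume and native-contact pairs
# See inst/templates/SCHEMA.md for the full schema.

# Physical forms: parameter slot count, which slots may be structure-derived
# ("?" placeholder), and the topology directive each form is emitted under.
.form_info <- list(
  harmonic_bond         = list(arity = 2L, derivable = c(TRUE, FALSE),        directive = "bonds"),
  harmonic_angle        = list(arity = 2L, derivable = c(TRUE, FALSE),        directive = "angles"),
  periodic_dihedral_1_3 = list(arity = 2L, derivable = c(TRUE, FALSE),        directive = "dihedrals"),
  contact_12_10         = list(arity = 2L, derivable = c(TRUE, FALSE),        directive = "pairs"),
  contact_gaussian      = list(arity = 3L, derivable = c(TRUE, FALSE, FALSE), directive = "pairs"),
  contact_harmonic      = list(arity = 2L, derivable = c(TRUE, FALSE),        directive = "pairs"),
  excluded_12           = list(arity = 2L, derivable = c(FALSE, FALSE),       directive = "atomtypes")
)

.template_files <- c(
  residues  = "residues.xml",
  settings  = "settings.xml",
  bonded    = "bonded.xml",
  nonbonded = "nonbonded.xml"
)

template_error <- function(file, context, msg) {
  stop(sprintf("template error [%s :: %s]: %s", file, context, msg), call. = FALSE)
}

#' Parse a forcefield template set
#'
#' Reads and validates the four XML documents that make up a template set
#' (residue definitions, settings/function declarations, bonded rules,
#' nonbonded rules). All cross-references are resolved at parse time: every
#' rule must name a declared function, every bond endpoint a declared atom,
#' and every literal type token must occur on at least one atom.
#'
#' If the directory contains a subdirectory `cg/` holding a second four-file
#' set, it is parsed as the coarse-graining partner template (the main set
#' then describes the atomistic input, the partner the coarse-grained output).
#'
#' @param path directory containing `residues.xml`, `settings.xml`,
#'   `bonded.xml` and `nonbonded.xml`.
#' @return an object of class `sbm_templates`.
#' @seealso [match_rule()], [resolve_placeholders()], [assemble_topology()]
#' @export
parse_template_set <- function(path) {
  if (!dir.exists(path)) {
    stop(sprintf("template directory not found: %s", path), call. = FALSE)
  }
  files <- file.path(path, .template_files)
  names(files) <- names(.template_files)
  missing <- !file.exists(files)
  if (any(missing)) {
    stop(sprintf("template set %s is missing file(s): %s",
                 path, paste(.template_files[missing], collapse = ", ")),
         call. = FALSE)
  }

  settings_doc <- xml2::read_xml(files[["settings"]])
  functions <- .parse_functions(settings_doc, files[["settings"]])
  settings  <- .parse_nonbonded_settings(settings_doc, files[["settings"]])

  residues <- .parse_residues(files[["residues"]])
  bonded   <- .parse_rules(files[["bonded"]],
                           kinds = c(bond = 2L, angle = 3L, dihedral = 4L),
                           token_tag = "bType", functions = functions)
  nb       <- .parse_rules(files[["nonbonded"]],
                           kinds = c(nonbond = 1L, pair = 2L),
                           token_tag = NA, functions = functions)

  tset <- structure(list(
    name            = basename(normalizePath(path)),
    path            = path,
    residues        = residues,
    functions       = functions,
    bonded_rules    = bonded,
    pair_rules      = Filter(function(r) r$kind == "pair", nb),
    nonbond_rules   = Filter(function(r) r$kind == "nonbond", nb),
    settings        = settings,
    cg_partner      = NULL
  ), class = "sbm_templates")

  .validate_template_set(tset)

  cg_dir <- file.path(path, "cg")
  if (dir.exists(cg_dir)) {
    tset$cg_partner <- parse_template_set(cg_dir)
  }
  tset
}

.parse_functions <- function(doc, file) {
  nodes <- xml2::xml_find_all(doc, "//functions/function")
  if (length(nodes) == 0L) {
    template_error(file, "functions", "no <function> declarations found")
  }
  out <- list()
  for (nd in nodes) {
    name  <- xml2::xml_attr(nd, "name")
    form  <- xml2::xml_attr(nd, "form")
    if (is.na(name) || is.na(form)) {
      template_error(file, xml2::xml_path(nd), "function needs 'name' and 'form' attributes")
    }
    if (!form %in% names(.form_info)) {
      template_error(file, name, sprintf("unknown physical form '%s'", form))
    }
    info  <- .form_info[[form]]
    arity <- xml2::xml_attr(nd, "arity")
    arity <- if (is.na(arity)) info$arity else as.integer(arity)
    if (arity != info$arity) {
      template_error(file, name,
                     sprintf("arity %d does not match form %s (expects %d slots)",
                             arity, form, info$arity))
    }
    if (name %in% names(out)) {
      template_error(file, name, "duplicate function declaration")
    }
    out[[name]] <- list(name = name, form = form, arity = arity,
                        directive = info$directive, derivable = info$derivable)
  }
  out
}

.parse_nonbonded_settings <- function(doc, file) {
  nd <- xml2::xml_find_first(doc, "//nonbonded_settings")
  if (inherits(nd, "xml_missing")) {
    template_error(file, "nonbonded_settings", "missing <nonbonded_settings> element")
  }
  num_attr <- function(attr, default = NULL) {
    v <- xml2::xml_attr(nd, attr)
    if (is.na(v)) {
      if (is.null(default)) template_error(file, "nonbonded_settings",
                                           sprintf("missing attribute '%s'", attr))
      return(default)
    }
    as.numeric(v)
  }
  s <- list(
    sigma_NC        = num_attr("sigma_NC"),
    epsilon_NC      = num_attr("epsilon_NC"),
    exclusion_depth = as.integer(num_attr("exclusion_depth", 3))
  )
  if (!isTRUE(s$sigma_NC > 0)) template_error(file, "nonbonded_settings", "sigma_NC must be > 0")
  if (!isTRUE(s$epsilon_NC >= 0)) template_error(file, "nonbonded_settings", "epsilon_NC must be >= 0")
  if (!isTRUE(s$exclusion_depth >= 1L)) template_error(file, "nonbonded_settings", "exclusion_depth must be >= 1")
  s
}

.parse_residues <- function(file) {
  doc <- xml2::read_xml(file)
  nodes <- xml2::xml_find_all(doc, "//residue")
  if (length(nodes) == 0L) template_error(file, "residues", "no <residue> elements")
  out <- list()
  for (nd in nodes) {
    name <- xml2::xml_attr(nd, "name")
    if (is.na(name)) template_error(file, xml2::xml_path(nd), "residue needs a 'name'")
    if (name %in% names(out)) template_error(file, name, "duplicate residue definition")
    rclass <- xml2::xml_attr(nd, "class")
    if (is.na(rclass)) rclass <- "amino"
    if (!rclass %in% c("amino", "nucleic", "ligand")) {
      template_error(file, name, sprintf("unknown residue class '%s'", rclass))
    }

    anodes <- xml2::xml_find_all(nd, "./atom")
    if (length(anodes) == 0L) template_error(file, name, "residue declares no atoms")
    atoms <- data.frame(
      name   = xml2::xml_attr(anodes, "name"),
      btype  = xml2::xml_attr(anodes, "bType"),
      nbtype = xml2::xml_attr(anodes, "nbType"),
      ptype  = xml2::xml_attr(anodes, "pType"),
      charge = suppressWarnings(as.numeric(xml2::xml_attr(anodes, "charge"))),
      mass   = suppressWarnings(as.numeric(xml2::xml_attr(anodes, "mass"))),
      stringsAsFactors = FALSE
    )
    # reduced-unit defaults: charge 0, mass 1
    atoms$charge[is.na(atoms$charge)] <- 0
    atoms$mass[is.na(atoms$mass)] <- 1
    if (anyNA(atoms$name) || any(atoms$name == "")) {
      template_error(file, name, "atom without a name")
    }
    if (anyDuplicated(atoms$name)) {
      template_error(file, name, sprintf("duplicate atom name '%s'",
                                         atoms$name[duplicated(atoms$name)][1]))
    }
    if (anyNA(atoms$btype) || anyNA(atoms$nbtype) || anyNA(atoms$ptype)) {
      template_error(file, name, "every atom needs bType, nbType and pType")
    }

    bnodes <- xml2::xml_find_all(nd, "./bond")
    bonds <- if (length(bnodes)) {
      cbind(xml2::xml_attr(bnodes, "a"), xml2::xml_attr(bnodes, "b"))
    } else {
      matrix(character(), ncol = 2)
    }
    for (k in seq_len(nrow(bonds))) {
      for (endpoint in bonds[k, ]) {
        if (!endpoint %in% atoms$name) {
          template_error(file, name,
                         sprintf("bond references undeclared atom '%s'", endpoint))
        }
      }
      if (bonds[k, 1] == bonds[k, 2]) {
        template_error(file, name, "bond joins an atom to itself")
      }
    }

    cnode <- xml2::xml_find_first(nd, "./connect")
    connect_out <- connect_in <- NA_character_
    if (!inherits(cnode, "xml_missing")) {
      connect_out <- xml2::xml_attr(cnode, "out")
      connect_in  <- xml2::xml_attr(cnode, "in")
      for (ca in c(connect_out, connect_in)) {
        if (!is.na(ca) && !ca %in% atoms$name) {
          template_error(file, name, sprintf("connect atom '%s' is not declared", ca))
        }
      }
    }

    out[[name]] <- list(name = name, class = rclass, atoms = atoms,
                        bonds = bonds, connect_out = connect_out,
                        connect_in = connect_in)
  }
  out
}

# Parse a rule document. `kinds` maps element name -> tuple length.
# Bonded rules use <bType> tokens; nonbonded use <nbType> (nonbond) and
# <pType> (pair) tokens.
.parse_rules <- function(file, kinds, token_tag, functions) {
  doc <- xml2::read_xml(file)
  rules <- list()
  seen <- character()
  for (kind in names(kinds)) {
    tag <- if (is.na(token_tag)) {
      if (kind == "nonbond") "nbType" else "pType"
    } else token_tag
    nodes <- xml2::xml_find_all(doc, sprintf("//%s", kind))
    for (nd in nodes) {
      func_str <- xml2::xml_attr(nd, "func")
      if (is.na(func_str)) template_error(file, xml2::xml_path(nd), "rule needs a 'func' attribute")
      parsed <- .parse_func_string(func_str, file, xml2::xml_path(nd))
      if (!parsed$name %in% names(functions)) {
        template_error(file, func_str,
                       sprintf("undeclared function '%s' referenced", parsed$name))
      }
      decl <- functions[[parsed$name]]
      if (length(parsed$params) != decl$arity) {
        template_error(file, func_str,
                       sprintf("function %s expects %d parameters, got %d",
                               parsed$name, decl$arity, length(parsed$params)))
      }
      bad <- parsed$placeholder & !decl$derivable[seq_along(parsed$placeholder)]
      if (any(bad)) {
        template_error(file, func_str,
                       sprintf("'?' placeholder in slot %d of %s, which is not structure-derivable",
                               which(bad)[1], decl$form))
      }
      tokens <- xml2::xml_text(xml2::xml_find_all(nd, sprintf("./%s", tag)))
      if (length(tokens) != kinds[[kind]]) {
        template_error(file, func_str,
                       sprintf("%s rule needs %d <%s> tokens, got %d",
                               kind, kinds[[kind]], tag, length(tokens)))
      }
      key_fwd <- paste(c(kind, tokens), collapse = "|")
      key_rev <- paste(c(kind, rev(tokens)), collapse = "|")
      if (key_fwd %in% seen || key_rev %in% seen) {
        template_error(file, func_str,
                       sprintf("duplicate rule for pattern (%s)", paste(tokens, collapse = ", ")))
      }
      seen <- c(seen, key_fwd)
      rules[[length(rules) + 1L]] <- list(
        kind = kind, pattern = tokens, func = parsed$name,
        params = parsed$params, placeholder = parsed$placeholder
      )
    }
  }
  rules
}

# "bond_harmonic(?,20000)" -> list(name, params numeric w/ NA at "?", placeholder)
.parse_func_string <- function(s, file, context) {
  m <- regmatches(s, regexec("^\\s*([A-Za-z0-9_]+)\\s*\\(([^)]*)\\)\\s*$", s))[[1]]
  if (length(m) != 3L) template_error(file, context, sprintf("cannot parse func string '%s'", s))
  raw <- trimws(strsplit(m[3], ",")[[1]])
  raw <- raw[raw != "" | seq_along(raw) <= length(raw)]
  placeholder <- raw == "?"
  params <- suppressWarnings(as.numeric(raw))
  if (any(is.na(params) & !placeholder)) {
    template_error(file, context, sprintf("non-numeric parameter in '%s'", s))
  }
  params[placeholder] <- NA_real_
  list(name = m[2], params = params, placeholder = placeholder)
}

.validate_template_set <- function(tset) {
  atoms <- do.call(rbind, lapply(tset$residues, `[[`, "atoms"))
  known <- list(
    bond = unique(atoms$btype), angle = unique(atoms$btype),
    dihedral = unique(atoms$btype),
    pair = unique(atoms$ptype), nonbond = unique(atoms$nbtype)
  )
  all_rules <- c(tset$bonded_rules, tset$pair_rules, tset$nonbond_rules)
  for (r in all_rules) {
    lit <- setdiff(r$pattern, "*")
    unknown <- setdiff(lit, known[[r$kind]])
    if (length(unknown)) {
      template_error(tset$path, sprintf("%s rule %s", r$kind, r$func),
                     sprintf("type token '%s' does not occur on any atom", unknown[1]))
    }
  }
  invisible(tset)
}

#' Select the most specific rule matching a type tuple
#'
#' Specificity is the number of literal (non-wildcard) tokens a rule matches
#' with; a tuple and its reversal are equivalent (two-body and higher
#' interactions are symmetric under path reversal). An exact tie between two
#' distinct rules of equal specificity is an error: the template is ambiguous
#' and must supply an exact rule.
#'
#' @param rules a list of rules from a parsed template set
#'   (e.g. `tset$bonded_rules`, `tset$pair_rules`).
#' @param types character vector of type tokens to match.
#' @param kind optional rule kind filter ("bond", "angle", "dihedral",
#'   "pair", "nonbond"); inferred from tuple length for bonded rules if the
#'   list holds several kinds.
#' @return the matching rule (a list with `func`, `params`, `placeholder`).
#' @export
match_rule <- function(rules, types, kind = NULL) {
  if (!is.null(kind)) rules <- Filter(function(r) r$kind == kind, rules)
  rules <- Filter(function(r) length(r$pattern) == length(types), rules)
  best <- NULL
  best_score <- -1L
  tie <- FALSE
  for (r in rules) {
    score <- .pattern_score(r$pattern, types)
    if (score < 0L) next
    if (score > best_score) {
      best <- r; best_score <- score; tie <- FALSE
    } else if (score == best_score) {
      tie <- TRUE
    }
  }
  if (is.null(best)) {
    stop(sprintf("unparameterized interaction: no rule matches type tuple (%s)",
                 paste(types, collapse = ", ")), call. = FALSE)
  }
  if (tie) {
    stop(sprintf("ambiguous template: two rules match (%s) with equal specificity; declare an exact rule",
                 paste(types, collapse = ", ")), call. = FALSE)
  }
  best
}

# score = max literal matches over tuple orientations; -1 if no match
.pattern_score <- function(pattern, types) {
  score_one <- function(tp) {
    ok <- pattern == "*" | pattern == tp
    if (all(ok)) sum(pattern != "*") else -1L
  }
  max(score_one(types), score_one(rev(types)))
}

#' Fill "?" placeholders of a rule with a structure-measured value
#'
#' Placeholder slots (declared with `?` in the template) receive the value
#' measured from the native structure, in the slot's native units (nm for
#' distances, radians for angles/dihedrals). Numeric slots pass through.
#'
#' @param rule a rule as returned by [match_rule()].
#' @param measured_value the native measurement, or `NULL` when the rule is
#'   fully numeric.
#' @return numeric parameter vector.
#' @export
resolve_placeholders <- function(rule, measured_value = NULL) {
  if (any(rule$placeholder)) {
    if (is.null(measured_value) || !is.finite(measured_value)) {
      stop(sprintf("rule %s has a '?' placeholder but no measured value was supplied",
                   rule$func), call. = FALSE)
    }
    params <- rule$params
    params[rule$placeholder] <- measured_value
    params
  } else {
    if (!is.null(measured_value)) {
      warning(sprintf("measured value supplied for fully numeric rule %s; ignored", rule$func))
    }
    rule$params
  }
}

#' Serialize a template set back to its four XML documents
#'
#' Writing then re-parsing reproduces the compiled representation exactly
#' (parse -> serialize -> parse is the identity).
#'
#' @param tset a parsed template set.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_template_set <- function(tset, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  fmt_num <- function(x) formatC(x, format = "g", digits = 15)

  ## residues.xml
  lines <- c("<residues>")
  for (r in tset$residues) {
    lines <- c(lines, sprintf('  <residue name="%s" class="%s">', r$name, r$class))
    for (k in seq_len(nrow(r$atoms))) {
      a <- r$atoms[k, ]
      lines <- c(lines, sprintf(
        '    <atom name="%s" bType="%s" nbType="%s" pType="%s" charge="%s" mass="%s"/>',
        a$name, a$btype, a$nbtype, a$ptype, fmt_num(a$charge), fmt_num(a$mass)))
    }
    for (k in seq_len(nrow(r$bonds))) {
      lines <- c(lines, sprintf('    <bond a="%s" b="%s"/>', r$bonds[k, 1], r$bonds[k, 2]))
    }
    if (!is.na(r$connect_out) || !is.na(r$connect_in)) {
      lines <- c(lines, sprintf('    <connect out="%s" in="%s"/>', r$connect_out, r$connect_in))
    }
    lines <- c(lines, "  </residue>")
  }
  lines <- c(lines, "</residues>")
  writeLines(lines, file.path(path, "residues.xml"))

  ## settings.xml
  lines <- c("<settings>", "  <functions>")
  for (f in tset$functions) {
    lines <- c(lines, sprintf('    <function name="%s" form="%s" arity="%d"/>',
                              f$name, f$form, f$arity))
  }
  lines <- c(lines, "  </functions>",
             sprintf('  <nonbonded_settings sigma_NC="%s" epsilon_NC="%s" exclusion_depth="%d"/>',
                     fmt_num(tset$settings$sigma_NC), fmt_num(tset$settings$epsilon_NC),
                     tset$settings$exclusion_depth),
             "</settings>")
  writeLines(lines, file.path(path, "settings.xml"))

  rule_xml <- function(r, tag) {
    pstr <- ifelse(r$placeholder, "?", vapply(r$params, fmt_num, ""))
    c(sprintf('  <%s func="%s(%s)">', r$kind, r$func, paste(pstr, collapse = ",")),
      sprintf("    <%s>%s</%s>", tag, r$pattern, tag),
      sprintf("  </%s>", r$kind))
  }
  lines <- "<bonded>"
  for (r in tset$bonded_rules) lines <- c(lines, rule_xml(r, "bType"))
  lines <- c(lines, "</bonded>")
  writeLines(lines, file.path(path, "bonded.xml"))

  lines <- "<nonbonded>"
  for (r in tset$nonbond_rules) lines <- c(lines, rule_xml(r, "nbType"))
  for (r in tset$pair_rules) lines <- c(lines, rule_xml(r, "pType"))
  lines <- c(lines, "</nonbonded>")
  writeLines(lines, file.path(path, "nonbonded.xml"))

  if (!is.null(tset$cg_partner)) {
    write_template_set(tset$cg_partner, file.path(path, "cg"))
  }
  invisible(path)
}

#' @export
print.sbm_templates <- function(x, ...) {
  cat(sprintf("Template set '%s': %d residues, %d functions, %d bonded rules, %d pair rules, %d nonbond rules\n",
              x$name, length(x$residues), length(x$functions),
              length(x$bonded_rules), length(x$pair_rules), length(x$nonbond_rules)))
  cat(sprintf("  nonbonded: sigma_NC=%g nm, epsilon_NC=%g, exclusion depth %d\n",
              x$settings$sigma_NC, x$settings$epsilon_NC, x$settings$exclusion_depth))
  if (!is.null(x$cg_partner)) cat(sprintf("  coarse-graining partner: '%s'\n", x$cg_partner$name))
  invisible(x)
}

# Look up the template atom entry for (residue name, atom name); NULL if absent.
.template_atom <- function(tset, resname, atom_name) {
  r <- tset$residues[[resname]]
  if (is.null(r)) return(NULL)
  k <- match(atom_name, r$atoms$name)
  if (is.na(k)) return(NULL)
  r$atoms[k, ]
}

#' Path to a bundled template set
#'
#' Bundled sets: `sbm_ca` (one C-alpha bead per residue, 12-10 native
#' contacts), `sbm_ca_gaussian` (Gaussian-well contacts), `sbm_aa` (all heavy
#' atoms, proper dihedrals only), `enm` (all-atom elastic network:
#' harmonic springs on all atom pairs within the cutoff, no bonded terms).
#'
#' @param name template set name.
#' @return directory path.
#' @export
bundled_template <- function(name = c("sbm_ca", "sbm_ca_gaussian", "sbm_aa", "enm")) {
  name <- match.arg(name)
  path <- system.file("templates", name, package = "sbmr")
  if (path == "") stop(sprintf("bundled template '%s' not found", name), call. = FALSE)
  path
}
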