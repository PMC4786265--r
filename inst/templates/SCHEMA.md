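# Template set XML schema

A template set is a directory with four XML documents. An optional `cg/`
subdirectory may hold a second four-file set, the coarse-graining partner
(the main set then matches the atomistic input structure, the partner the
coarse-grained output).

## residues.xml

```xml
<residues>
  <residue name="ALA" class="amino">
    <atom name="CA" bType="CA" nbType="CA" pType="CA" charge="0" mass="1"/>
    <bond a="N" b="CA"/>              <!-- intra-residue covalent bonds -->
    <connect out="C" in="N"/>         <!-- inter-residue linkage atoms -->
  </residue>
</residues>
```

* `class`: one of `amino`, `nucleic`, `ligand` (default `amino`).
* Each atom carries three type tokens: `bType` selects bonded rules,
  `nbType` selects excluded-volume (nonbond) rules, `pType` selects
  native-contact (pair) rules.
* `charge` and `mass` default to 0 and 1 (reduced units).
* `connect`: consecutive residues within a chain are joined by a bond from
  the previous residue's `out` atom to the next residue's `in` atom.
* Atom names must be unique within a residue; every bond endpoint and
  connect atom must be a declared atom.

## settings.xml

```xml
<settings>
  <functions>
    <function name="bond_harmonic" form="harmonic_bond" arity="2"/>
    ...
  </functions>
  <nonbonded_settings sigma_NC="0.4" epsilon_NC="1.0" exclusion_depth="3"/>
</settings>
```

Physical forms and their parameter slots (a `?` marks slots that may be
structure-derived):

| form                    | slots                        | emitted under |
|-------------------------|------------------------------|---------------|
| `harmonic_bond`         | (r0? nm, eps_b)              | bonds         |
| `harmonic_angle`        | (theta0? rad, eps_theta)     | angles        |
| `periodic_dihedral_1_3` | (phi0? rad, eps_D)           | dihedrals     |
| `contact_12_10`         | (r0? nm, eps_C)              | pairs         |
| `contact_gaussian`      | (r0? nm, eps_C, width nm)    | pairs         |
| `contact_harmonic`      | (r0? nm, k)                  | pairs         |
| `excluded_12`           | (sigma nm, eps_NC)           | atomtypes     |

`exclusion_depth` is the bond-graph distance within which atom pairs are
excluded from the generic nonbonded interaction (GROMACS `nrexcl`
semantics).

## bonded.xml

```xml
<bonded>
  <bond func="bond_harmonic(?,20000)">
    <bType>*</bType>
    <bType>*</bType>
  </bond>
  <angle func="...">  3 bType tokens  </angle>
  <dihedral func="..."> 4 bType tokens </dihedral>
</bonded>
```

`*` is a whole-token wildcard. A rule applies to a type tuple if every
token matches literally or by wildcard, in either tuple orientation
(interactions are symmetric under path reversal). The most specific rule
(largest number of literal matches) wins; an equal-specificity tie between
distinct rules is an error. The `?` placeholder requests that the slot be
filled with the value measured from the native structure.

## nonbonded.xml

```xml
<nonbonded>
  <nonbond func="excluded_12(0.4,1.0)">
    <nbType>*</nbType>               <!-- one token: per-atom-type -->
  </nonbond>
  <pair func="contact_12_10(?,1.0)">
    <pType>*</pType>
    <pType>*</pType>
  </pair>
</nonbonded>
```

At most one rule per exact pattern (a pattern and its reversal count as the
same pattern); duplicates are a parse error.
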