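<settings>
  <functions>
    <function name="bond_harmonic" form="harmonic_bond" arity="2"/>
    <function name="angle_harmonic" form="harmonic_angle" arity="2"/>
    <function name="dihedral_sbm" form="periodic_dihedral_1_3" arity="2"/>
    <function name="contact_gaussian" form="contact_gaussian" arity="3"/>
    <function name="excluded_12" form="excluded_12" arity="2"/>
  </functions>
  <nonbonded_settings sigma_NC="0.4" epsilon_NC="1.0" exclusion_depth="3"/>
</settings>
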