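<settings>
  <functions>
    <function name="contact_harmonic" form="contact_harmonic" arity="2"/>
    <function name="excluded_12" form="excluded_12" arity="2"/>
  </functions>
  <nonbonded_settings sigma_NC="0.25" epsilon_NC="1.0" exclusion_depth="1"/>
</settings>
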