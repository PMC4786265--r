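kind	atoms_per_residue	fixed_n	geometry
dimer	1	2	two CA beads 0.38 nm apart along z
triatomic_bent	1	3	three CA beads, 0.38 nm arms, 100 degree interior angle at the middle bead
planar_four	1	4	four CA beads, 0.38 nm bonds, 110 degree angles, dihedral = phi argument (0 cis, pi trans)
ca_helix	1	NA	ideal alpha-helix CA trace, 100 deg/residue twist, radius/rise scaled for exactly 0.38 nm consecutive spacing
ca_hairpin	1	NA	two antiparallel zigzag strands (0.334 nm x-step, +/-0.09 nm z-zigzag), strands 0.5 nm apart in y
two_chain	1	NA	two ca_helix traces (chains A and B) separated by 2.0 nm in x
ci2_synthetic	2	64	synthetic 64-residue alpha/beta fold: helix packed on a four-stranded sheet; CA plus CB sidechain centroid at 0.25 nm (no CB for GLY)
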