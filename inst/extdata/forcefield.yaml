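# Non-bonded force-field parameters, version 1.
#
# Seven-type atomic classification: 1 aliphatic carbon, 2 sp2/aromatic
# carbon, 3 neutral nitrogen, 4 neutral oxygen, 5 sulfur, 6 charged
# nitrogen/oxygen (Lys/Arg amines, carboxylates), 7 polar (amide) hydrogen.
#
# Values are documented stand-ins assembled from standard published van der
# Waals well depths/radii and atomic solvation parameters; they are not the
# original laboratory parameter set.  Units: r0 Angstrom, eps kJ/mol,
# etr kJ/mol/A^2 (transfer energy per unit accessible area, positive =
# hydrophobic, i.e. favourable transfer out of water), charges in fractions
# of the unit charge (assigned per residue/atom in code).
version: 1
types:
  - {id: 1, label: C_sp3,    r0: 1.80, eps: 0.40, etr:  0.080, hydrophobic: true}
  - {id: 2, label: C_sp2,    r0: 1.75, eps: 0.35, etr:  0.050, hydrophobic: true}
  - {id: 3, label: N_neutral, r0: 1.55, eps: 0.55, etr: -0.050, hydrophobic: false}
  - {id: 4, label: O_neutral, r0: 1.52, eps: 0.60, etr: -0.060, hydrophobic: false}
  - {id: 5, label: S,         r0: 1.80, eps: 1.00, etr:  0.045, hydrophobic: true}
  - {id: 6, label: charged,   r0: 1.55, eps: 0.70, etr: -0.110, hydrophobic: false}
  - {id: 7, label: H_polar,   r0: 1.00, eps: 0.10, etr: -0.030, hydrophobic: false}
# radius of a water molecule (Angstrom); also the ASA probe radius
rsol: 1.4
probe_radius: 1.4
# Coulomb: E = k * qi * qj / (eps(d) * d), k in kJ*A/mol/e^2; the
# dielectric rises sigmoidally (smoothstep) from eps_low at d <= d_low nm
# to eps_high at d >= d_high nm of interatomic separation
coulomb_k: 1389.35
dielectric: {d_low_nm: 0.2, d_high_nm: 1.0, eps_low: 1.0, eps_high: 80.0}
# non-bonded evaluation cutoff (Angstrom) for the sampling engine
cutoff: 8.0
# implicit DPPC bilayer: the water-phase interface function
#   C(z) = 1 / (1 + exp(alpha * (z0 - |z|)))
# is fitted so that C = 1e-3 at |z| = 1.35 nm and 1 - 1e-3 at 1.8 nm.
# (An alternative exponential decay constant of 1/0.9 A^-1 is reported for
# related transfer-energy profiles; the plateau fit takes precedence here.)
membrane:
  core_half_width_nm: 1.35
  water_bound_nm: 1.8
  plateau_tolerance: 1.0e-3
  alip: 0.018
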