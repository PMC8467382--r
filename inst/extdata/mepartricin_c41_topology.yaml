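# Coupling topology for the C40-C42 stretch around the C41 stereocenter,
# using the fragment atom names of the built-in blueprint.
#
# Substituent electronegativity groups are this package's assumed mapping
# (the assignment is not uniquely fixed by the published group table):
#   OH (1.33)       - the C41 hydroxyl oxygen
#   CH2CH2R (0.76)  - the chain carbon on the C39 side
#   CH2C(O)R (0.72) - the chain carbon toward the C43 carbonyl
#   H (0)           - geminal protons (listing them is optional)
atoms:
  - C39
  - C40
  - C41
  - C42
  - C43
  - O41
  - H40a
  - H40b
  - H41
  - H42a
  - H42b
couplings:
  - label: H40a/H41
    proton_a: H40a
    carbon_a: C40
    carbon_b: C41
    proton_b: H41
    substituents:
      - {atom: C39, site: carbon_a, group: CH2CH2R}
      - {atom: H40b, site: carbon_a, group: H}
      - {atom: O41, site: carbon_b, group: OH}
      - {atom: C42, site: carbon_b, group: CH2C(O)R}
  - label: H40b/H41
    proton_a: H40b
    carbon_a: C40
    carbon_b: C41
    proton_b: H41
    substituents:
      - {atom: C39, site: carbon_a, group: CH2CH2R}
      - {atom: H40a, site: carbon_a, group: H}
      - {atom: O41, site: carbon_b, group: OH}
      - {atom: C42, site: carbon_b, group: CH2C(O)R}
  - label: H41/H42a
    proton_a: H41
    carbon_a: C41
    carbon_b: C42
    proton_b: H42a
    substituents:
      - {atom: O41, site: carbon_a, group: OH}
      - {atom: C40, site: carbon_a, group: CH2CH2R}
      - {atom: C43, site: carbon_b, group: CH2C(O)R}
      - {atom: H42b, site: carbon_b, group: H}
  - label: H41/H42b
    proton_a: H41
    carbon_a: C41
    carbon_b: C42
    proton_b: H42b
    substituents:
      - {atom: O41, site: carbon_a, group: OH}
      - {atom: C40, site: carbon_a, group: CH2CH2R}
      - {atom: C43, site: carbon_b, group: CH2C(O)R}
      - {atom: H42a, site: carbon_b, group: H}
measured:
  - {label: H40a/H41, j_hz: 4.5}
  - {label: H40b/H41, j_hz: 8.5}
  - {label: H41/H42a, j_hz: 3.2}
  - {label: H41/H42b, j_hz: 9.3}
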