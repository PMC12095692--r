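# Default pharmacophore feature-typing ruleset.
#
# The six feature kinds (donor, acceptor, anion, cation, hydrophobe, ring)
# follow the standard color-feature vocabulary of ligand-based screening.
# The rules are data so that users can tune them; the commercial assigners'
# exact definitions are unpublished, so no parity with them is claimed.
donor:
  # N or O carrying at least one explicit hydrogen
  elements: [N, O]
acceptor:
  # N or O with a lone pair: formal charge <= 0 and not a donor-only case;
  # positively charged N/O are excluded
  elements: [N, O]
anion:
  # formally negative atoms, plus neutral carboxylic acids (deprotonated at
  # pH 7.4); the feature sits at the centroid of the charged group
  include_carboxylic_acid: true
cation:
  # formally positive atoms, plus aliphatic primary/secondary amines with
  # >= 2 substituent H (protonated at pH 7.4)
  include_aliphatic_amine: true
hydrophobe:
  # connected clusters of carbons having no N/O/charged neighbours; one
  # feature per cluster at its centroid
  min_cluster_size: 2
ring:
  # one feature per smallest-set-of-smallest-rings ring, at its centroid
  max_ring_size: 8
radii:
  # feature Gaussian radius in Angstrom, used by color scoring
  default: 1.0
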