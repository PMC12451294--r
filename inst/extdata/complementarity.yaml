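# Ligand-feature <-> protein-feature complementarity with interaction
# distance thresholds (Angstroms). One table serves both training-data
# extraction and validity scoring.
rules:
  - {ligand: HydrogenDonor,    protein: HydrogenAcceptor, threshold: 4.0}
  - {ligand: HydrogenAcceptor, protein: HydrogenDonor,    threshold: 4.0}
  - {ligand: Hydrophobic,      protein: Hydrophobic,      threshold: 5.0}
  - {ligand: Aromatic,         protein: Aromatic,         threshold: 5.0}
  - {ligand: Aromatic,         protein: PositiveIon,      threshold: 5.0}
  - {ligand: PositiveIon,      protein: Aromatic,         threshold: 5.0}
  - {ligand: NegativeIon,      protein: PositiveIon,      threshold: 5.0}
  - {ligand: PositiveIon,      protein: NegativeIon,      threshold: 5.0}
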