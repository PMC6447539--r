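{
  "comment": "Species library: chemical formula and molecular-volume anchors (T in deg C, V in cubic angstrom). Volumes between anchors are linearly interpolated, outside they are linearly extrapolated from the nearest segment. Provenance: solvent volumes from tabulated mass densities; DMPC gel/fluid volumes from dilatometric literature values with the 40 C anchor consistent with fluid-phase thermal expansion; aescin and cholesterol volumes back-computed from their literature neutron scattering length densities (1.42e-6 and 0.22e-6 per square angstrom) and are labelled as such.",
  "species": [
    {
      "name": "D2O",
      "formula": "D2O",
      "volume_anchors": [[10, 30.0697], [40, 30.2284]],
      "note": "from densities 1.10586 and 1.10005 g/cm3 at 10 and 40 C"
    },
    {
      "name": "H2O",
      "formula": "H2O",
      "volume_anchors": [[10, 29.9318], [40, 30.1581]],
      "note": "from densities 0.9997 and 0.9922 g/cm3"
    },
    {
      "name": "DMPC",
      "formula": "C36H72NO8P",
      "volume_anchors": [[10, 1041], [30, 1101], [40, 1114]],
      "note": "gel 1041 A^3 (10 C), fluid 1101 A^3 (30 C) from dilatometry; 1114 A^3 at 40 C back-computed from the fluid-phase NSLD"
    },
    {
      "name": "cholesterol",
      "formula": "C27H46O",
      "volume_anchors": [[25, 602.32]],
      "note": "temperature-independent; back-computed from NSLD 0.22e-6 A^-2"
    },
    {
      "name": "aescin",
      "formula": "C55H86O24",
      "volume_anchors": [[25, 1290.48]],
      "note": "temperature-independent; back-computed from NSLD 1.42e-6 A^-2"
    }
  ]
}
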