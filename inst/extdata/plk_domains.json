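{
  "_comment": "Approximate canonical Plk domain boundaries, 1-based inclusive columns on a 576-residue Polo-frame alignment. These are conventions for the template only: replace start/end values with coordinates curated for your own alignment before interpreting per-domain tests. The two PBD residues required for substrate binding (His518, Lys520 in D. melanogaster Polo coordinates) fall inside PB2.",
  "kinase": [30, 290],
  "linker": [291, 410],
  "PBD": [411, 576],
  "PB1": [411, 490],
  "PB2": [505, 576]
}
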