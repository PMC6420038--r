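{
  "comment": "Default torsion-angle region map. Within each group boxes are tried in order and the first containing (phi, psi) wins; the last box of a group is the absorbing default. Boxes are [phiMin, phiMax, psiMin, psiMax] in degrees; min > max denotes a wrapped interval across the +/-180 seam.",
  "helix": [
    {"descriptor": 1, "box": [-140, -30, -90, 30]},
    {"descriptor": 2, "box": [20, 140, -30, 100]},
    {"descriptor": 3, "box": [-180, -30, 60, -150]},
    {"descriptor": 4, "box": [-180, 180, -180, 180]}
  ],
  "strand": [
    {"descriptor": 5, "box": [-180, -45, 85, -155]},
    {"descriptor": 6, "box": [-140, -30, -60, 50]},
    {"descriptor": 7, "box": [-180, 180, -180, 180]}
  ],
  "coil": [
    {"descriptor": 8, "box": [-180, -45, 85, -155]},
    {"descriptor": 9, "box": [-140, -30, -90, 40]},
    {"descriptor": 10, "box": [-180, 180, -180, 180]}
  ]
}
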