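{
  "weights": {
    "A": -2.45268387062404,
    "R": 6.1458195747508,
    "N": -0.751952605628356,
    "D": -3.40445458130606,
    "C": -0.336005510084209,
    "E": 3.217713876434,
    "Q": -0.53776988744606,
    "G": -0.667056301957964,
    "H": -0.189101862407924,
    "I": 0.16105445518629,
    "L": -2.89963836744209,
    "K": 5.80422869211276,
    "M": -0.474202444220437,
    "F": 0.415223395726799,
    "P": -1.0592402588304,
    "S": -0.00627585077272157,
    "T": -0.267582903884027,
    "W": -0.160118174259125,
    "Y": -0.139015365393746,
    "V": -2.3989420099535
  },
  "bias": 0.0775068686101069,
  "provenance": "synthetic default: linear SVM on composition fractions trained once on the package binding fixture (40 K/R/E-enriched binders vs 40 acidic/hydrophobic non-binders, seed 20251001)"
}
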