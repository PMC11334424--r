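{
  "clusters": {
    "S0001": 1,
    "S0002": 1,
    "S0003": 1,
    "S0004": 1,
    "S0005": 1,
    "S0006": 1,
    "S0007": 1,
    "S0008": 1,
    "S0009": 1,
    "S0010": 1,
    "S0011": 1,
    "S0012": 1,
    "S0013": 2,
    "S0014": 2,
    "S0015": 2,
    "S0016": 2,
    "S0017": 2,
    "S0018": 2,
    "S0019": 2,
    "S0020": 2,
    "S0021": 2,
    "S0022": 2,
    "S0023": 2,
    "S0024": 2,
    "S0025": 3,
    "S0026": 3,
    "S0027": 3,
    "S0028": 3,
    "S0029": 3,
    "S0030": 3,
    "S0031": 3,
    "S0032": 3,
    "S0033": 3,
    "S0034": 3,
    "S0035": 3,
    "S0036": 3
  },
  "markers": {
    "1": ["K00049", "K00065", "K00074", "K00146", "K00122"],
    "2": ["K00150", "K00128", "K00047", "K00024", "K00071"],
    "3": ["K00100", "K00089", "K00110", "K00020", "K00114"]
  },
  "gcKOs": ["K00111", "K00131", "K00041", "K00139", "K00027"],
  "archaeaRichCluster": 1,
  "scenario": {
    "nClusters": 3,
    "samplesPerCluster": [12, 12, 12],
    "nKOs": 150,
    "markersPerCluster": 5,
    "markerDelta": 4,
    "baselineLogMean": 6,
    "baselineLogSD": 2,
    "depthLogMean": 17,
    "depthLogSD": 0.5,
    "gcMeans": [0.62, 0.45, 0.45],
    "gcSD": 0.03,
    "nGCLinkedKOs": 5,
    "gcBeta": 8,
    "archaeaRichCluster": 1,
    "contigsPerSample": 2000,
    "seed": 42
  }
}
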