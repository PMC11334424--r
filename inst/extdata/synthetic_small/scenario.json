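{
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
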