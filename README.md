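# HiCflux

Time-resolved Hi-C analysis of chromatin reorganization after condensate
disruption.

## Scientific context

Biomolecular condensates — liquid-like assemblies of proteins and RNA —
are thought to help organize the three-dimensional genome. A direct way
to test their contribution is to dissolve them transiently (for example
with 1,6-hexanediol), take Hi-C snapshots at several timepoints during
treatment and after withdrawal, and ask which features of genome folding
are lost, which are strengthened, and which recover. Typical signatures
in such timecourses are the loss of long-range (&gt; 5 Mb) contacts,
transient strengthening and homogenization of A/B compartmentalization,
localized compartment switches of differing reversibility, TAD boundary
fusions/shifts/separations, and the disappearance of condensate-associated
long-range point interactions.

HiCflux implements the statistics needed to quantify each of these
signatures, together with a synthetic-data generator that plants all of
them with known ground truth, so every estimator in the package is
validated against planted truth rather than against another tool.

## What the package provides

* **Matrix handling** — triplet/bedGraph/BED/JSON I/O, depth
  equalization by exact without-replacement downsampling, ICE balancing,
  observed/expected transforms (`readTriplets`, `downsampleToMin`,
  `iceBalance`, `oeTransform`).
* **Distance decay** — relative contact probability curves, per-distance
  fold changes, changed-interaction fractions (`rcp`, `rcpFoldChange`,
  `changedFraction`).
* **Compartments** — PC1 of the O/E correlation matrix with signal-track
  orientation, TAD-level smoothing, per-bin strength, saddle plots and
  segregation scores, interaction homogeneity, and a multi-timepoint
  switch classifier with onset/recovery subtypes (`computePC1`,
  `smoothByTADs`, `perBinStrength`, `saddle`, `homogeneity`,
  `classifySwitch`).
* **TADs** — TopDom-style calling, direction indices, replicate-aware
  differential boundary testing, fusion/shift/separation classification,
  aggregate TAD analysis, boundary-recovery F1 (`callTADs`,
  `testBoundaryChange`, `classifyReorganization`, `ata`, `boundaryF1`).
* **Interactions** — TAD-pair aggregation with a robust lowess distance
  background, hypergeometric significance calls with an O/E floor,
  signal-based classification, aggregate peak analysis
  (`aggregateTADPairs`, `callSignificant`, `apa`).
* **Enrichment** — fold enrichment of signal tracks in called regions,
  region-vs-rest tests, boundary peak density profiles
  (`foldEnrichment`, `regionVsRestTest`, `boundaryPeakDensity`).
* **Imaging statistics** — Ripley's K and L functions, mean squared
  displacement, diffusion-coefficient fits (`ripleyK`, `msd`,
  `fitDiffusion`).
* **Simulation & pipeline** — planted-truth generators for contact maps,
  timecourses, signal tracks, point patterns and trajectories, plus an
  end-to-end deterministic pipeline (`simulateContactMap`,
  `simulateTimecourse`, `runPipeline`).

Classes follow Bioconductor conventions: S4 objects (`ContactMatrix`,
`CompartmentProfile`, `TADSet`, `SignalTrack`, `PlantedTruth`,
`SimConfig`) with validity methods, accessor generics and `show`
methods.

## Worked example

```r
library(HiCflux)

cfg <- simConfig(nBins = 300L, depth = 6e5, seed = 7, tadBoost = 3)
sim <- simulateContactMap(cfg)          # replicates + planted truth
cm  <- mergeReplicates(sim$matrices)
bal <- iceBalance(cm)
oe  <- oeTransform(bal)
bal
#> ContactMatrix (balanced) chrS: 300 bins x 40000 bp, total = 1,174,807, masked bins = 6

## compartments: recover the planted profile
prof <- computePC1(oe, simulateSignalTrack(trueProfile(sim$truth), seed = 7))
abs(cor(pc1(prof), trueProfile(sim$truth), use = "complete.obs"))
#> 0.857

## TADs: recover the planted boundaries
ts <- callTADs(bal)
boundaryF1(boundaries(ts), trueBoundaries(sim$truth))$f1
#> 0.979  (23 boundaries called)

## loops: aggregate peak analysis at the planted anchors
res <- apa(oe, loopAnchors(sim$truth))
res$centerScore / res$cornerMean
#> 2.66  (over 20 anchor pairs)
```

For a timecourse, build a `perturbationSchedule` (attenuation,
amplitude multipliers, homogenization, loop attenuation, planted
switches and TAD events per timepoint) and pass it to
`simulateTimecourse`, or run the whole analysis with:

```r
runPipeline(pipelineConfig(seed = 42L), "out/")
```

which writes per-stage tables and a `manifest.json` of MD5 checksums;
rerunning the same configuration reproduces every file byte for byte.

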