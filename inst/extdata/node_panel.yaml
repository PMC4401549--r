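# Default signaling-node panel: (modulator, exposure time, readout, metric,
# target population). Short-term signaling nodes are read on cPARP-negative
# (healthy) blasts; 24-hour apoptosis nodes on total viable blasts with the
# 24-hour untreated well as the unmodulated reference; the viability-loss
# node on intact cells.
nodes:
  - {modulator: AraC+Dauno, time_hr: 24, readout: cPARP, metric: Uu, population: blast}
  - {modulator: AraC+Dauno, time_hr: 24, readout: CD34, metric: Uu, population: blast}
  - {modulator: AraC, time_hr: 24, readout: CD34, metric: Uu, population: blast}
  - {modulator: AraC, time_hr: 24, readout: cPARP, metric: Uu, population: blast}
  - {modulator: FLT3L, time_hr: 0.25, readout: pAKT, metric: log2Fold, population: healthy_blast}
  - {modulator: FLT3L, time_hr: 0.25, readout: pAKT, metric: Uu, population: healthy_blast}
  - {modulator: PMA, time_hr: 0.25, readout: pCREB, metric: log2Fold, population: healthy_blast}
  - {modulator: IL-27, time_hr: 0.25, readout: pSTAT3, metric: Uu, population: healthy_blast}
  - {modulator: unmodulated, time_hr: 0.25, readout: pAKT, metric: Basal, population: healthy_blast}
  - {modulator: unmodulated, time_hr: 0.25, readout: pAKT, metric: Ua, population: healthy_blast}
  - {modulator: unmodulated, time_hr: 0.25, readout: cPARP, metric: PhIntact, population: blast}
  - {modulator: unmodulated, time_hr: 0.25, readout: CD34, metric: PctPos, population: blast}
  - {modulator: AraC+Dauno, time_hr: 24, readout: AquaAmine, metric: Uu, population: intact}
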