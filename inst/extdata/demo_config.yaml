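# Demo configuration: three pooled samples from a five-strain founding
# mixture, with one HGT fragment planted in the first sample.
seed: 1
simulate:
  genome_length: 20000
  n_contigs: 2
  divergence: 0.01
  mean_coverage: 60
  n_samples: 3
  hgt:
    - donor: S2
      contig: ctg1
      start: 3000
      end: 5500
      frequency: 0.5
      carrier_samples: [1]
strainfreq:
  min_depth: 10
popgen:
  window: 5000
  step: 2500
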