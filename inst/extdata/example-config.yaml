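# Example pipeline configuration: two treatment classes whose scenes differ
# in migration speed (control-like vs high-dose-like motility).
seed: 1
classes:
  - name: control
    nVideos: 3
    scene:
      nCells: 12
      nFrames: 40
      fieldWidth: 256
      fieldHeight: 256
      speedMean: 3.5
      speedSd: 0.5
      turnConcentration: 0.4
      noiseSd: 5
  - name: atp50
    nVideos: 3
    scene:
      nCells: 12
      nFrames: 40
      fieldWidth: 256
      fieldHeight: 256
      speedMean: 2.0
      speedSd: 0.5
      turnConcentration: 0.3
      noiseSd: 5
detection:
  blurSigma: 2
  threshold: 125
tracking:
  redetectInterval: 10
contacts:
  contactRadius: 16
evolution:
  generations: 3000
trainFraction: 0.67
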