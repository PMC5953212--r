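# Packaged study defaults: synthetic prostate case, seven coplanar 6 MV
# beams, 78 Gy in 2 Gy fractions, population-based verification.
seed: 1
phantom:
  spacing: [1.91, 1.91, 2.5]   # mm, (LR, AP, SI)
  ctv_semiaxes: [21, 19, 23]   # mm
uncertainty:
  sigma_sys: [1.1, 1.5, 1.1]   # mm, (LR, AP, SI)
  sigma_rand: [2.2, 3.2, 2.1]  # mm, (LR, AP, SI)
  sigma_penumbra: 3.2          # mm
beams:
  count: 7
  start: 0
prescription: 78               # Gy
fraction_dose: 2               # Gy
population: 50000
rectum_max_levels: [70, 65, 60]
objectives:
  - {structure: prostate, dmin: 74.5, su: 10, dmax: 82.0, so: 10}
  - {structure: rectum, dmax: 70.0, so: 8}
  - {structure: bladder, dmax: 70.0, so: 6}
  - {structure: femoral_heads, dmax: 50.0, so: 2}
  - {structure: external, dmax: 60.0, so: 2}
dose:
  mu: 0.005                    # 1/mm
  beamlet_size: [5, 5]         # mm
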