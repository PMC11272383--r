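# Baseline rate constants and conversion factors for the batch-culture
# nucleotide-oxidation model (model A), plus the extra constants and
# re-fitted overrides carried by each structural variant.
# Nominal units: first-order rates in s^-1, bimolecular rates in M^-1 s^-1,
# half-saturation constants in M, CellVol in ml, molML in molecules per ml
# of a 1 M solution, GCperGen in GC base pairs per genome.
baseline:
  U1: 2.66e-1
  M1: 2.69e-4
  Ks: 3.97e-5
  I1: 6.90e-3
  D1: 6.90e-3
  O2: 12.0
  I2: 2.53e-4
  D2: 2.00e-4
  C1: 2.8
  C2: 3.50e-4
  R1: 2.00e-4
  S: 2.58e-2
  r: 17.3
  O3: 5.60e+1
  R2: 2.53e-4
  Met1: 1545.0
  CellVol: 1.03e-12
  molML: 6.02e+20
  GCperGen: 2357528.0
variants:
  A: {}
  B:
    extra:
      U2: 6.7e-3
      K2: 1.82e-4
  C:
    extra:
      ROSC: 1.8e-7
  D:
    overrides:
      O2: 40.0
    extra:
      ROSC2: 6.0e-11
      kdiff: 70.0
  E:
    extra:
      C3: 1.5e-4
  F:
    extra:
      C3a: 3.5e-6
  G:
    overrides:
      O2: 70.0
    extra:
      C3G: 2.6e-3
  H:
    extra:
      C3b: 8.0e-10
  I:
    overrides:
      O2: 130.0
    extra:
      C3c: 1.98e-7
  J:
    overrides:
      O2: 6.36e-4
    extra:
      Kt: 4.8e+7
  K:
    overrides:
      r: 175.0
    extra:
      kAhp: 6.6e-4
      kmAhp: 1.2e-6
      kKat: 4.9e-1
      kmKat: 5.9e-3
      kdiff: 70.0
  D_coculture:
    overrides:
      O2: 40.0
    extra:
      ROSC2: 6.0e-11
      kdiff: 70.0
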