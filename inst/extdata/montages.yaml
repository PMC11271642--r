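# Channel montages for movement-intention detection.
#
# custom: left-hemisphere/midline selections centred on C1 (the focus of
#   right-arm movement planning activity); smaller sets are nested subsets of
#   larger ones, shrinking concentrically around C1. No even-indexed
#   (right-hemisphere) labels appear. The exact memberships are an editable
#   approximation of a motor-centred selection.
# standard: extended 10-20 constellations; standard-32 is the first bank of
#   the 64-channel cap layout.
custom:
  "4": [C1, C3, FC1, CP1]
  "8": [C1, C3, FC1, CP1, FC3, CP3, Cz, C5]
  "16": [C1, C3, FC1, CP1, FC3, CP3, Cz, C5,
         F1, F3, FC5, CP5, P1, P3, CPz, Pz]
  "21": [C1, C3, FC1, CP1, FC3, CP3, Cz, C5,
         F1, F3, FC5, CP5, P1, P3, CPz, Pz,
         F5, T7, TP7, P5, Fz]
  "32": [C1, C3, FC1, CP1, FC3, CP3, Cz, C5,
         F1, F3, FC5, CP5, P1, P3, CPz, Pz,
         F5, T7, TP7, P5, Fz,
         Fp1, AF7, AF3, F7, FT7, FT9, TP9, P7, PO7, PO3, POz]
standard:
  "16": [Fp1, Fp2, F7, F3, F4, F8, T7, C3, C4, T8,
         P7, P3, P4, P8, O1, O2]
  "21": [Fp1, Fp2, F7, F3, Fz, F4, F8, T7, C3, Cz, C4, T8,
         P7, P3, Pz, P4, P8, O1, Oz, O2, POz]
  "32": [Fp1, Fp2, F7, F3, Fz, F4, F8, FC5, FC1, FC2, FC6,
         T7, C3, Cz, C4, T8, TP9, CP5, CP1, CP2, CP6, TP10,
         P7, P3, Pz, P4, P8, PO9, O1, Oz, O2, PO10]
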