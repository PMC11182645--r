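Synthetic pKa-predictor summary fixture (active D2 conformation).
This file mimics the empirical predictor's .pka summary dialect; it is a
hand-written stand-in, not real predictor output.
-------------------------------------------------------------------------------
SUMMARY OF THIS PREDICTION
       Group      pKa  model-pKa   ligand atom-type
   ASP 136 A     3.40       3.80
   ASP 138 A    12.40       3.80
   GLU 140 A     6.40       4.50
   TYR 141 A    10.10      10.00
-------------------------------------------------------------------------------
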