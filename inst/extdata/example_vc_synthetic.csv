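pressure_mpa,percent
-0.25,7.94
-0.75,-1.0899
-1.25,4.5742
-1.75,7.5269
-2.25,8.8552
-2.75,10.0199
-3.25,23.5003
-3.75,22.8973
-4.25,42.9968
-4.75,43.7767
-5.25,62.4341
-5.75,78.5286
-6.25,69.6851
-6.75,82.6634
-7.25,88.7829
-7.75,96.3459
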