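angle_deg
139.358304999769
233.387000709772
170.630210833624
219.434149833396
218.133670105599
74.2068376578391
248.484868006781
303.920701732859
187.990641086362
54.8851548414677
310.620811069384
231.405575419776
164.066606196575
228.069433243945
111.298747672699
243.621826507151
265.537630864419
353.380127730779
238.324462319724
113.356075077318
298.552736355923
77.7569338632748
116.09638874419
200.515970075503
232.788297543302
50.9677672432736
177.353293793276
232.604718273506
251.972209238447
185.970796546899
158.027396975085
91.8767602555454
322.593359034508
336.577370306477
156.705604162998
288.503377935849
237.066735201515
228.883368051611
250.703355940059
267.908689426258
289.495904780924
312.066124845296
80.8776044659317
223.710991661064
202.699446883053
108.821066566743
300.929446793161
170.826559597626
303.880700441077
352.7594397543
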