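# Plausibility ranges for measured risk factors; records with any measured
# value outside its range are dropped before analysis. Ranges are data, not
# code, so alternative cleaning protocols can be swapped in.
# Units: sbp/dbp mmHg, height m, weight kg, bmi kg/m^2, waist cm,
# fpg and total_chol mg/dl.
sbp: [70, 270]
dbp: [30, 150]
height: [1.00, 2.50]
weight_kg: [12, 300]
bmi: [10, 80]
waist: [30, 200]
fpg: [45, 540]
total_chol: [67, 773]
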