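model stem_cell
note dimensionless concentrations (hematopoietic lineage choice)
param eN = 0.5
param eM = 0.5
var x1 in [0, 6] : eN - x1
var x2 in [0, 6] : 5*x1/(1 + x1) * 1/(1 + x3^4) - x2
var x3 in [0, 6] : 5*x4/(1 + x4) * 1/(1 + x2^4) - x3
var x4 in [0, 6] : eM/(1 + x2^4) - x4
var x5 in [0, 6] : x1*x4/(1 + x1*x4) + 4*x3/(1 + x3) * 1/(1 + x2^4) - x5
var x6 in [0, 6] : x1*x4/(1 + x1*x4) + 4*x2/(1 + x2) * 1/(1 + x3^4) - x6
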