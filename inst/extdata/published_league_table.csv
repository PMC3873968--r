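group,band,strategy,cost,qaly,reported_optimal
target,50-54,none,475,20.49,FALSE
target,50-54,surveil2y,1892,20.54,TRUE
target,50-54,surveil1y,2640,20.55,FALSE
target,50-54,screen2y,6311,20.58,FALSE
target,50-54,screen2y_surveil1y,8191,20.61,FALSE
target,55-59,none,534,18.62,FALSE
target,55-59,surveil2y,1879,18.67,TRUE
target,55-59,surveil1y,2554,18.69,FALSE
target,55-59,screen2y,5846,18.72,FALSE
target,55-59,screen2y_surveil1y,7671,18.76,FALSE
target,60-64,none,592,16.58,FALSE
target,60-64,surveil2y,1854,16.64,FALSE
target,60-64,surveil1y,2451,16.66,TRUE
target,60-64,screen2y,5328,16.70,FALSE
target,60-64,screen2y_surveil1y,7081,16.74,FALSE
target,65-69,none,632,14.43,FALSE
target,65-69,surveil2y,1804,14.50,FALSE
target,65-69,surveil1y,2321,14.51,TRUE
target,65-69,screen2y,4759,14.55,FALSE
target,65-69,screen2y_surveil1y,6413,14.59,FALSE
male,50-54,none,621,19.57,FALSE
male,50-54,surveil2y,2002,19.64,FALSE
male,50-54,surveil1y,2716,19.66,TRUE
male,50-54,screen2y,6225,19.71,FALSE
male,50-54,screen2y_surveil1y,8114,19.75,FALSE
male,55-59,none,705,17.64,FALSE
male,55-59,surveil2y,2015,17.71,FALSE
male,55-59,surveil1y,2655,17.73,FALSE
male,55-59,screen2y,5769,17.79,FALSE
male,55-59,screen2y_surveil1y,7621,17.85,TRUE
male,60-64,none,784,15.54,FALSE
male,60-64,surveil2y,2000,15.63,FALSE
male,60-64,surveil1y,2561,15.65,FALSE
male,60-64,screen2y,5263,15.72,FALSE
male,60-64,screen2y_surveil1y,7036,15.79,TRUE
male,65-69,none,844,13.37,FALSE
male,65-69,surveil2y,1968,13.45,FALSE
male,65-69,surveil1y,2449,13.48,FALSE
male,65-69,screen2y,4712,13.56,FALSE
male,65-69,screen2y_surveil1y,6406,13.64,TRUE
female,50-54,none,341,21.35,FALSE
female,50-54,surveil2y,1795,21.39,TRUE
female,50-54,surveil1y,2579,21.40,FALSE
female,50-54,screen2y,6407,21.41,FALSE
female,50-54,screen2y_surveil1y,8268,21.43,FALSE
female,55-59,none,380,19.53,FALSE
female,55-59,surveil2y,1764,19.57,TRUE
female,55-59,surveil1y,2477,19.58,FALSE
female,55-59,screen2y,5930,19.60,FALSE
female,55-59,screen2y_surveil1y,7744,19.62,FALSE
female,60-64,none,420,17.52,FALSE
female,60-64,surveil2y,1725,17.56,TRUE
female,60-64,surveil1y,2361,17.57,FALSE
female,60-64,screen2y,5401,17.59,FALSE
female,60-64,screen2y_surveil1y,7146,17.63,FALSE
female,65-69,none,448,15.36,FALSE
female,65-69,surveil2y,1664,15.41,TRUE
female,65-69,surveil1y,2219,15.42,FALSE
female,65-69,screen2y,4816,15.44,FALSE
female,65-69,screen2y_surveil1y,6485,15.49,FALSE
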