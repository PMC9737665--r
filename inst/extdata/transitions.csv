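"analyte","q1","q3","ce","polarity"
"alanine",90.1,44.2,13,"positive"
"arginine",175.02,60,16,"positive"
"asparagine",133.1,74,19,"positive"
"aspartate",134,74,17,"positive"
"cystine",241.002,74,32,"positive"
"glutamate",148.1,84.1,17,"positive"
"glutamine",147.1,84.1,17,"positive"
"histidine",156.1,110.1,14,"positive"
"isoleucine",132.1,86,13,"positive"
"leucine",132.1,86,13,"positive"
"lysine",147,67,32,"positive"
"methionine",150.1,133,12,"positive"
"phenylalanine",166.1,103,30,"positive"
"proline",116.1,70.1,13,"positive"
"serine",106,60,15,"positive"
"threonine",120,74,13,"positive"
"tryptophan",205,146,18,"positive"
"tyrosine",182.1,77,39,"positive"
"valine",118.1,55.2,13,"positive"
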