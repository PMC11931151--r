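compound,e_homo,e_lumo,ip,ea,gap,electronegativity,hardness,delta_n_max
Eucalyptol,-5.242,1.161,5.242,-1.161,6.403,2.040,3.201,0.637
Citronellol,-5.121,0.007,5.121,-0.007,5.128,2.557,2.564,0.997
3-7 dimethyl-2-octen-1-ol,-5.122,0.009,5.122,-0.009,5.131,2.556,2.565,0.996
2-camphol acetate,-6.046,-0.653,6.046,0.653,5.393,3.349,2.696,1.242
b-mercene,-5.238,-1.506,5.238,1.506,3.732,3.372,1.866,1.807
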