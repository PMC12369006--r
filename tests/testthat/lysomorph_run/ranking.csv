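"feature","biomarker","frame","fdr","n_a","n_b"
"LCCCD","lys-cell","cartesian",85.4826580145906,20,20
"LNCCD","lys-nuc","cartesian",61.8733075227917,20,20
"HLVR","lys-nuc","cartesian",47.6276545241795,20,20
"NLNSA","lys-nuc","cartesian",41.0212031038455,20,20
"LNRG","lys-nuc","spherical",20.0486399865904,20,20
"NRP","nuc-cell","spherical",17.7515493734242,20,20
"NNCCD","nuc-cell","cartesian",17.3740695300843,20,20
"LNPSSE_AzEl","lys-nuc","spherical",15.8998615495387,20,20
"LCPSSE_AzEl","lys-cell","spherical",9.26994748012752,20,20
"NCPSSE_AzEl","nuc-cell","spherical",5.20354305823025,20,20
"NCVR","nuc-cell","cartesian",2.58965335754067,20,20
"LVF","lys-cell","cartesian",2.54970700618727,20,20
"LNPSSE_Az","lys-nuc","spherical",2.41484731601257,20,20
"LNPSSE_El","lys-nuc","spherical",1.24763396321092,20,20
"LCMP","lys-cell","cartesian",0.55419645948269,20,20
"NSPH","nuc-cell","cartesian",0.424265780412176,20,20
"LRM","lys-cell","spherical",0.142730926122362,20,20
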