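"treated","control","feature","biomarker","frame","median_treated","median_control","pv","u","p_value","n_treated","n_control","stars","p_bh","flag_pv_undefined"
"KO","WT","NLNSA","lys-nuc","cartesian",0.233984375,0.53203125,-56.0205580029369,0,6.73833174897126e-08,20,20,"***",8.18225998089368e-08,FALSE
"KO","WT","HLVR","lys-nuc","cartesian",0.934620834188074,0.581313633351407,60.7773808434132,400,1.45088891038497e-11,20,20,"***",2.46651114765445e-11,FALSE
"KO","WT","LNPSSE_AzEl","lys-nuc","spherical",430.487702987242,30.1448229326811,1328.06512398033,400,1.45088891038497e-11,20,20,"***",2.46651114765445e-11,FALSE
"KO","WT","LNPSSE_Az","lys-nuc","spherical",258.533438555634,18.1951712991785,1320.89037967621,390,2.01673558543511e-09,20,20,"***",3.11677317749062e-09,FALSE
"KO","WT","LNPSSE_El","lys-nuc","spherical",109.973925475291,9.64543584527134,1040.16543409187,400,1.45088891038497e-11,20,20,"***",2.46651114765445e-11,FALSE
"KO","WT","LNCCD","lys-nuc","cartesian",0.716866647260979,0.0664179999374868,979.325857351471,400,1.45088891038497e-11,20,20,"***",2.46651114765445e-11,FALSE
"KO","WT","LNRG","lys-nuc","spherical",0.46066011977665,0.224503378375347,105.19072947155,400,1.45088891038497e-11,20,20,"***",2.46651114765445e-11,FALSE
"KO","WT","NNCCD","nuc-cell","cartesian",0.276870880035831,0.00323403364603195,8461.16263278653,400,1.45088891038497e-11,20,20,"***",2.46651114765445e-11,FALSE
"KO","WT","NSPH","nuc-cell","cartesian",0.666404892853621,0.689426869714199,-3.33929208040895,95,0.00388500574214169,20,20,"**",0.00412781860102555,FALSE
"KO","WT","NCVR","nuc-cell","cartesian",0.0790480578882558,0.107260839727602,-26.3029656592235,18,2.3170695898848e-08,20,20,"***",3.03001407908012e-08,FALSE
"KO","WT","NCPSSE_AzEl","nuc-cell","spherical",124.888225028081,0.617886583658576,20112.160019498,400,1.45088891038497e-11,20,20,"***",2.46651114765445e-11,FALSE
"KO","WT","NRP","nuc-cell","spherical",0.276313758655544,0.00320822807554939,8512.65945402671,400,1.45088891038497e-11,20,20,"***",2.46651114765445e-11,FALSE
"KO","WT","LCPSSE_AzEl","lys-cell","spherical",255.948907741055,31.1622376017149,721.343162234825,400,1.45088891038497e-11,20,20,"***",2.46651114765445e-11,FALSE
"KO","WT","LVF","lys-cell","cartesian",0.0261260047045574,0.0341979363241482,-23.6035635106171,18,2.3170695898848e-08,20,20,"***",3.03001407908012e-08,FALSE
"KO","WT","LRM","lys-cell","spherical",0.691578681437398,0.699748201998387,-1.16749432691049,138,0.0964995524361003,20,20,"ns",0.0964995524361003,FALSE
"KO","WT","LCMP","lys-cell","cartesian",0.0451586021429388,0.0534501938212813,-15.5127438940009,91,0.00264263059155935,20,20,"**",0.0029949813371006,FALSE
"KO","WT","LCCCD","lys-cell","cartesian",0.420943159825289,0.0670161404477718,528.122056884708,400,1.45088891038497e-11,20,20,"***",2.46651114765445e-11,FALSE
"WT","KO","NLNSA","lys-nuc","cartesian",0.53203125,0.233984375,127.378964941569,400,6.73833174897126e-08,20,20,"***",8.18225998089368e-08,FALSE
"WT","KO","HLVR","lys-nuc","cartesian",0.581313633351407,0.934620834188074,-37.8021961326802,0,1.45088891038497e-11,20,20,"***",2.46651114765445e-11,FALSE
"WT","KO","LNPSSE_AzEl","lys-nuc","spherical",30.1448229326811,430.487702987242,-92.9975182279308,0,1.45088891038497e-11,20,20,"***",2.46651114765445e-11,FALSE
"WT","KO","LNPSSE_Az","lys-nuc","spherical",18.1951712991785,258.533438555634,-92.9621594015727,10,2.01673558543511e-09,20,20,"***",3.11677317749062e-09,FALSE
"WT","KO","LNPSSE_El","lys-nuc","spherical",9.64543584527134,109.973925475291,-91.2293429523542,0,1.45088891038497e-11,20,20,"***",2.46651114765445e-11,FALSE
"WT","KO","LNCCD","lys-nuc","cartesian",0.0664179999374868,0.716866647260979,-90.7349574441413,0,1.45088891038497e-11,20,20,"***",2.46651114765445e-11,FALSE
"WT","KO","LNRG","lys-nuc","spherical",0.224503378375347,0.46066011977665,-51.2648547731466,0,1.45088891038497e-11,20,20,"***",2.46651114765445e-11,FALSE
"WT","KO","NNCCD","nuc-cell","cartesian",0.00323403364603195,0.276870880035831,-98.8319343494652,0,1.45088891038497e-11,20,20,"***",2.46651114765445e-11,FALSE
"WT","KO","NSPH","nuc-cell","cartesian",0.689426869714199,0.666404892853621,3.45465303563347,305,0.00388500574214169,20,20,"**",0.00412781860102555,FALSE
"WT","KO","NCVR","nuc-cell","cartesian",0.107260839727602,0.0790480578882558,35.690670451674,382,2.3170695898848e-08,20,20,"***",3.03001407908012e-08,FALSE
"WT","KO","NCPSSE_AzEl","nuc-cell","spherical",0.617886583658576,124.888225028081,-99.5052483262376,0,1.45088891038497e-11,20,20,"***",2.46651114765445e-11,FALSE
"WT","KO","NRP","nuc-cell","spherical",0.00320822807554939,0.276313758655544,-98.8389184486652,0,1.45088891038497e-11,20,20,"***",2.46651114765445e-11,FALSE
"WT","KO","LCPSSE_AzEl","lys-cell","spherical",31.1622376017149,255.948907741055,-87.8248210251235,0,1.45088891038497e-11,20,20,"***",2.46651114765445e-11,FALSE
"WT","KO","LVF","lys-cell","cartesian",0.0341979363241482,0.0261260047045574,30.8961577205207,382,2.3170695898848e-08,20,20,"***",3.03001407908012e-08,FALSE
"WT","KO","LRM","lys-cell","spherical",0.699748201998387,0.691578681437398,1.18128577127472,262,0.0964995524361003,20,20,"ns",0.0964995524361003,FALSE
"WT","KO","LCMP","lys-cell","cartesian",0.0534501938212813,0.0451586021429388,18.3610459245338,309,0.00264263059155935,20,20,"**",0.0029949813371006,FALSE
"WT","KO","LCCCD","lys-cell","cartesian",0.0670161404477718,0.420943159825289,-84.0795273937729,0,1.45088891038497e-11,20,20,"***",2.46651114765445e-11,FALSE
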