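"cell_id","condition","tsne1","tsne2"
"WT_001","WT",105.664779505162,70.9426560502518
"WT_002","WT",86.3481387032769,98.8756104633296
"WT_003","WT",75.6632485524197,55.4279550723722
"WT_004","WT",-32.7269987407819,50.0044379548046
"WT_005","WT",124.918755173184,102.230569779344
"WT_006","WT",98.8316882158683,136.645021191382
"WT_007","WT",13.7156236393126,55.8832858948331
"WT_008","WT",35.9679905920316,114.495545009805
"WT_009","WT",63.9944683015148,121.820388436302
"WT_010","WT",69.6305048290071,160.375324309708
"WT_011","WT",-34.5951047740607,104.167589609023
"WT_012","WT",87.3716032588076,25.4375586349707
"WT_013","WT",-15.4976215229908,24.7391680452609
"WT_014","WT",-3.47258840361206,76.3150686522117
"WT_015","WT",18.3631615644285,146.148597125938
"WT_016","WT",23.2359904492022,28.4360935292325
"WT_017","WT",26.4719201518137,88.2179327745706
"WT_018","WT",56.364112235317,91.8531587376659
"WT_019","WT",-5.00505196741102,127.773954029104
"WT_020","WT",50.4747187579753,61.4713288102835
"KO_001","KO",65.1846150478324,212.489697104319
"KO_002","KO",-87.8175831779788,-76.116259165815
"KO_003","KO",-42.1348822088242,-82.7237546634802
"KO_004","KO",86.6794076412858,-88.6000806836226
"KO_005","KO",-166.141558844515,-65.8032340809501
"KO_006","KO",-65.2042574183557,-135.755021827857
"KO_007","KO",-62.2977582004024,-101.434071312948
"KO_008","KO",-117.851827378339,-31.5167296535434
"KO_009","KO",-123.233650470581,-236.999925613141
"KO_010","KO",-36.9889458648112,-150.243577900586
"KO_011","KO",-21.7094332781651,-57.0552934727375
"KO_012","KO",-67.0532043568602,-54.8051576103024
"KO_013","KO",-124.097142306988,-102.709807637449
"KO_014","KO",-31.2429442462292,-113.580175799655
"KO_015","KO",-105.454079950516,-118.742148733747
"KO_016","KO",44.2523713053617,-130.373879941342
"KO_017","KO",17.2121023816193,-109.309976915278
"KO_018","KO",-11.5702337141694,-89.76141198971
"KO_019","KO",-7.41224713628738,-136.015204505411
"KO_020","KO",11.161913656458,-72.2052297071377
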