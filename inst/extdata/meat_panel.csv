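species,sequence,precursor_mz,product_mz,rt,ce,product_ion
beef,TLEDQVNELK,594.808967,845.436323,7.142,19.4,y7
beef,GLSDSVSIGPVTVK,679.879924,899.556044,9.465,22.1,y9
beef,FLEELLTTQC,762.871773,1006.49861,10.549,24.6,NA
chicken,LVSWYDNEFGYSNR,875.397001,1264.52291,14.072,28.1,y10
chicken,IGDEFVADLDQLQR,809.907201,1057.56365,12.472,26.1,y9
chicken,LDVPISGEPAPTVTWK,855.45907,1382.73144,11.566,27.5,y13
chicken,ECQTLVSDVDYR,742.83793,966.489087,9.529,24.0,y8
duck,VVFDDSFDR,550.256371,901.368637,8.38,18.1,y7
duck,IVESLQSSLDAEIR,780.417402,1018.51636,9.645,25.2,y9
duck,LAILENANVLAR,648.885344,999.558169,10.535,21.1,y9
pork,VNVDEVGGEALGR,657.836048,887.458121,7.124,21.4,y9
pork,DQGSYEDFVEGLR,757.841527,1127.53677,10.346,24.5,y9
lamb,SPPNPENIAPGYSGPLK,869.443951,1342.70014,7.954,28.0,y13
lamb,HVLTTLGER,513.290548,789.446494,5.044,16.9,y7
lamb,NLVHIITHGEEKD,752.891354,1041.52112,6.188,24.3,y9
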