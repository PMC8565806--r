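generation,drug,total,serious
1st,ceftezole,2325,168
1st,cefathiamidine,815,44
1st,cefazolin pentahydrate,240,13
1st,cefazolin,169,16
1st,cefazedone,65,2
1st,cefadroxil,37,2
1st,cefalexin,17,0
1st,cefradine,16,1
1st,cefalotin,2,0
1st,cefalexin/trimethoprim,1,0
2nd,cefamandole nafate,1589,73
2nd,cefuroxime,1394,77
2nd,cefotiam,231,9
2nd,cefaclor,150,7
2nd,cefprozil,23,0
2nd,cefuroxime axetil,14,1
2nd,cefonicid,3,0
3rd,ceftazidime,1692,126
3rd,cefoperazone/sulbactam,1565,143
3rd,cefotaxime,1328,104
3rd,ceftriaxone,1128,82
3rd,cefoperazone/tazobactam,924,60
3rd,ceftizoxime,700,35
3rd,ceftriaxone/tazobactam,425,33
3rd,cefotaxime/sulbactam,314,27
3rd,cefixime,253,12
3rd,cefmenoxime,97,1
3rd,cefodizime,93,6
3rd,cefoperazone,56,4
3rd,cefpiramide,56,0
3rd,cefdinir,55,2
3rd,cefpodoxime proxetil,6,0
3rd,ceftazidime/tazobactam,4,1
3rd,ceftriaxone/sulbactam,1,0
3rd,ceftizoxime/sulbactam,1,0
4th,cefepime,64,2
4th,cefoselis,1,0
unknown,unknown,3,1
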