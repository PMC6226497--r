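windowLength,nDU,nAU,nDB,nAB
0.003148,411142,54781,59667,406255
0.003111,430657,44173,79577,395253
0.007082,194513,19943,26189,188267
0.004229,387519,44660,69389,362790
0.003452,307992,48706,47134,309564
0.005848,265259,42379,37660,269978
0.004414,345546,49089,71513,323122
0.008689,134788,19079,30326,123541
0.003883,322111,40686,67636,295161
0.004218,351412,30614,50421,331605
0.006148,250106,32991,30155,252942
0.005124,337170,50475,56189,331456
0.003815,414592,59277,66258,407611
0.008177,180506,21665,36452,165720
0.006598,252964,31953,41734,243184
0.002839,422578,53428,86654,389352
0.002884,451947,39344,76057,415233
0.01267,132098,14896,24738,122256
0.00605,256148,33851,54631,235368
0.004296,282081,42052,58794,265339
0.002674,414804,46809,58637,402975
0.008441,139215,16270,24693,130791
0.002771,438861,56696,78593,416964
0.003308,423438,55229,72743,405925
0.01021,116595,16380,20910,112065
0.005808,273986,31699,56965,248720
0.004711,221471,34610,30098,225984
0.003246,398612,63683,65077,397218
0.00578,252579,26209,33611,245177
0.002765,380766,53636,53473,380928
0.004215,342017,53021,42741,352297
0.003125,375101,49321,48273,376150
0.005827,225153,30091,42958,212285
0.004589,323104,50964,65115,308952
0.01792,88270,13310,12776,88803
0.003811,383444,49723,54260,378906
0.01347,89626,13308,11138,91795
0.006948,167169,15894,22092,160971
0.002742,404408,58233,86360,376281
0.00419,304237,40475,59023,285688
0.006886,229435,22389,45462,206361
0.004375,251043,23266,33353,240956
0.01189,102573,12399,21513,93460
0.003977,427377,62039,91565,397851
0.007116,238882,33818,52570,220131
0.0037,420703,62327,94040,388991
0.003222,414047,41055,66815,388287
0.004528,307333,48658,67200,288791
0.003676,440712,47675,61381,427006
0.004878,316624,30911,44091,303444
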