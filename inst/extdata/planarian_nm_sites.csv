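molecule,label,position,base,class
18S,Am28,28,A,full
18S,Am755,755,A,full
18S,Um1228,1228,U,full
18S,Gm1258,1258,G,full
18S,Um1266,1266,U,full
18S,Gm1268,1268,G,full
18S,Am1323,1323,A,full
18S,Um1377,1377,U,full
18S,Gm1425,1425,G,full
18S,Cm1638,1638,C,full
18S,Gm152,152,G,partial
18S,Am161,161,A,partial
18S,Am338,338,A,partial
18S,Gm358,358,G,partial
18S,Gm642,642,G,partial
18S,Am647,647,A,partial
18S,Um665,665,U,partial
18S,Gm866,866,G,partial
18S,Gm936,936,G,partial
18S,Gm1017,1017,G,partial
18S,Gm1325,1325,G,partial
18S,Am1326,1326,A,partial
18S,Gm1426,1426,G,partial
18S,Am1754,1754,A,partial
28S,Am312,312,A,full
28S,Gm313,313,G,full
28S,Gm935,935,G,full
28S,Am937,937,A,full
28S,Am947,947,A,full
28S,Am1049,1049,A,full
28S,Am1266,1266,A,full
28S,Cm1587,1587,C,full
28S,Am1599,1599,A,full
28S,Gm1600,1600,G,full
28S,Um181,181,U,partial
28S,Gm204,204,G,partial
28S,Am315,315,A,partial
28S,Gm397,397,G,partial
28S,Am504,504,A,partial
28S,Gm551,551,G,partial
28S,Am880,880,A,partial
28S,Gm987,987,G,partial
28S,Gm1048,1048,G,partial
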