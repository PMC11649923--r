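molecule,label,position,base,source
18S,Am28,28,A,cross_species_annotation
18S,Um1228,1228,U,cross_species_annotation
18S,Um1266,1266,U,cross_species_annotation
18S,Gm1268,1268,G,cross_species_annotation
18S,Am1323,1323,A,cross_species_annotation
18S,Um1377,1377,U,cross_species_annotation
18S,Gm1425,1425,G,cross_species_annotation
18S,Cm1638,1638,C,cross_species_annotation
28S,Gm935,935,G,cross_species_annotation
28S,Am937,937,A,cross_species_annotation
28S,Am947,947,A,cross_species_annotation
28S,Am1266,1266,A,cross_species_annotation
28S,Cm1587,1587,C,cross_species_annotation
28S,Am1599,1599,A,cross_species_annotation
28S,Gm1600,1600,G,cross_species_annotation
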