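order,genus,n_samples,mean_xo,mean_xy,mean_multixy
Blattodea,Cryptotermes,6,23,16.4,NA
Dermaptera,Forficula,14,11,10.8,NA
Dermaptera,Nala,3,17.5,17,NA
Dermaptera,Nesogaster,2,10,9,NA
Mantodea,Deiphobe,2,9,NA,12
Orthoptera,Aleuas,6,9,9.2,NA
Orthoptera,Dichroplus,35,10.74,8.7,19
Orthoptera,Diponthus,7,10.5,10,NA
Orthoptera,Eurotettix,5,10,9,NA
Orthoptera,Gryllotalpa,5,9.67,5,NA
Orthoptera,Isophya,25,15,14,NA
Orthoptera,Leiotettix,10,11,8,5.5
Orthoptera,Scotussa,8,10.6,8.5,9
Orthoptera,Scyllina,3,11,10,NA
Orthoptera,Tetrixocephalus,5,11,10,NA
Orthoptera,Xyleus,9,11,10,NA
Orthoptera,Zoniopoda,6,11,10,NA
Phasmatodea,Didymuria,11,17.6,NA,14.67
Phasmatodea,Isagoras,3,18,NA,16
Phasmatodea,Leptynia,5,18.25,NA,17
Phasmatodea,Podacanthus,3,17,NA,13
Phasmatodea,Prisopus,2,24,NA,13
Plecoptera,Perla,7,9.5,4,11.75
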