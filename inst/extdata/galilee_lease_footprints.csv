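group,proponent,tenement_id,lease_area_ha,affected_area_ha,open_cut_ha,underground_ha,other_ha
Adani,Adani,EPC1080 (east portion only),18714,32112,17424,9507,5181
Adani,Adani,EPC1690,26016,NA,NA,NA,NA
Alpha/Kevin's Corner,Alpha/Kevin's Corner,EPC1210,36818,50649,12969,18238,19441
Alpha/Kevin's Corner,Alpha/Kevin's Corner,MDL285,33682,NA,NA,NA,NA
Alpha/Kevin's Corner,Alpha/Kevin's Corner,MDL333,31480,NA,NA,NA,NA
China First,China First,EPC1040,75674,53881,NA,27630,19084
China First,China First,EPC1079,63863,NA,NA,NA,NA
China Stone,China Stone,EPC987 (south portion only),20066,16787,NA,NA,5795
South Galilee,South Galilee,EPC1049,89523,14823,NA,NA,5305
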