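re,total_km2,free_km2,pct_free,n_recent_records,subregion
7.12.24a,4,4,100.0,0,Townsville Plains
7.12.65b,1,1,100.0,0,Townsville Plains
9.8.1a,113,10,9.3,0,Cape-Campaspe Plains / Undara-Toomba Basalts
9.12.1a,4,4,100.0,0,Broken River
10.3.6a,840,101,12.0,1,Cape-Campaspe Plains
10.3.28a,851,36,4.3,25,Alice Tableland / Cape Campaspe Plains
10.4.5,85,0,0.0,9,Alice Tableland / Cape Campaspe Plains
10.5.1a,134,3,2.5,2,Alice Tableland / Cape Campaspe Plains
10.5.5a,3030,501,16.5,36,Cape-Campaspe Plains
10.7.11a,189,33,17.2,1,Alice Tableland / Cape Campaspe Plains
11.3.12,214,207,97.0,169,Townsville Plains
11.3.25b,168,127,75.4,90,Townsville Plains
11.3.27,8,6,78.2,3,Townsville Plains
11.3.30,349,268,76.9,534,Townsville Plains
11.3.31,82,73,89.1,14,Townsville Plains
11.3.35,586,491,83.8,527,Townsville Plains
11.3.35a,195,186,95.4,4,Townsville Plains
11.11.9,203,187,92.0,0,Cape River Hills
11.11.15,222,187,84.1,0,Beucazon Hills
11.12.1,365,177,48.6,0,Townsville Plains / Bogie River Hills / Beucazon Hills / Belyando Downs
11.12.9,140,136,96.8,8,Townsville Plains
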