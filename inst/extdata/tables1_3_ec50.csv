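id,p1,p2,p3,p4,p5,p6,p7,p8,p9,p10,p11,ec50_nM,censored,emax_pct,pec50,series,in_training_31
RXL-100,His,Aib,Glu,Gly,Thr,Phe,Thr,Ser,Asp,Bip,Bip,0.5,FALSE,109.6,NA,parent,TRUE
RXL-3000,His,Aib,Glu,Gly,Thr,Phe(2-F),Thr,Ser,Asp,Bip,Bip,0.1,FALSE,109.2,9.92,parent,TRUE
RXL-101,His,Aib,Glu,Gly,Thr,aMe-Phe(2-F),Thr,Ser,Asp,Bip,Bip,0.01,FALSE,116.7,10.89,parent,TRUE
RXL-3010,His,Aib,Glu,Gly,Thr,Phe(2-Br),Thr,Ser,Asp,Bip,Bip,3.85,FALSE,120.6,NA,phe6_mod,TRUE
RXL-3011,His,Aib,Glu,Gly,Thr,Phe(2-Cl),Thr,Ser,Asp,Bip,Bip,0.9,FALSE,91.3,NA,phe6_mod,TRUE
RXL-3012,His,Aib,Glu,Gly,Thr,Phe(2-CF3),Thr,Ser,Asp,Bip,Bip,13.9,FALSE,99.3,NA,phe6_mod,TRUE
RXL-3013,His,Aib,Glu,Gly,Thr,Phe(2-CH3),Thr,Ser,Asp,Bip,Bip,2.1,FALSE,98.6,NA,phe6_mod,TRUE
RXL-3014,His,Aib,Glu,Gly,Thr,Phe(2-NO2),Thr,Ser,Asp,Bip,Bip,1.1,FALSE,104.5,NA,phe6_mod,TRUE
RXL-3015,His,Aib,Glu,Gly,Thr,Phe(2-CN),Thr,Ser,Asp,Bip,Bip,7.7,FALSE,101,NA,phe6_mod,TRUE
RXL-3016,His,Aib,Glu,Gly,Thr,Phe(3-CF3),Thr,Ser,Asp,Bip,Bip,13.9,FALSE,108.9,NA,phe6_mod,TRUE
RXL-3039,His,Aib,Glu,Gly,Thr,"Phe(2,6-F)",Thr,Ser,Asp,Bip,Bip,0.16,FALSE,NA,NA,phe6_mod,FALSE
RXL-3017,His,Aib,Glu,Gly,Thr,"Phe(3,4,5-F)",Thr,Ser,Asp,Bip,Bip,7.2,FALSE,113.1,NA,phe6_mod,FALSE
RXL-3018,His,Aib,Glu,Gly,Thr,"Phe(2,3,4,5,6-F)",Thr,Ser,Asp,Bip,Bip,0.3,FALSE,102.5,NA,phe6_mod,FALSE
RXL-3019,His,Aib,Glu,Gly,Thr,Hph,Thr,Ser,Asp,Bip,Bip,16.0,FALSE,109.5,NA,phe6_mod,FALSE
RXL-3020,His,Aib,Glu,Gly,Thr,aMe-Phe,Thr,Ser,Asp,Bip,Bip,0.02,FALSE,107.9,NA,phe6_mod,FALSE
RXL-3021,His,Aib,Glu,Gly,Thr,Tyr,Thr,Ser,Asp,Bip,Bip,3.0,FALSE,100.2,NA,phe6_mod,FALSE
RXL-3022,His,Aib,Glu,Gly,Thr,D-Phe,Thr,Ser,Asp,Bip,Bip,23.2,FALSE,101.4,NA,phe6_mod,FALSE
RXL-3023,His,Aib,Glu,Gly,Thr,Trp,Thr,Ser,Asp,Bip,Bip,13.8,FALSE,106.3,NA,phe6_mod,FALSE
RXL-3024,His,Aib,Glu,Gly,Thr,Bip,Thr,Ser,Asp,Bip,Bip,10.8,FALSE,102.3,NA,phe6_mod,FALSE
RXL-3001,Ala,Aib,Glu,Gly,Thr,Phe(2-F),Thr,Ser,Asp,Bip,Bip,21.9,FALSE,107.5,7.86,ala_scan,TRUE
RXL-3002,His,Ala,Glu,Gly,Thr,Phe(2-F),Thr,Ser,Asp,Bip,Bip,0.2,FALSE,102.5,9.92,ala_scan,TRUE
RXL-3003,His,Aib,Ala,Gly,Thr,Phe(2-F),Thr,Ser,Asp,Bip,Bip,7.9,FALSE,108.2,8.47,ala_scan,TRUE
RXL-3037,His,Aib,Glu,Ala,Thr,Phe(2-F),Thr,Ser,Asp,Bip,Bip,210.0,FALSE,73.8,6.46,ala_scan,TRUE
RXL-3004,His,Aib,Glu,Gly,Ala,Phe(2-F),Thr,Ser,Asp,Bip,Bip,7.7,FALSE,108.2,8.16,ala_scan,TRUE
RXL-3038,His,Aib,Glu,Gly,Thr,Ala,Thr,Ser,Asp,Bip,Bip,NA,TRUE,37.4,5.55,ala_scan,TRUE
RXL-3005,His,Aib,Glu,Gly,Thr,Phe(2-F),Ala,Ser,Asp,Bip,Bip,47.5,FALSE,102.4,7.67,ala_scan,TRUE
RXL-3006,His,Aib,Glu,Gly,Thr,Phe(2-F),Thr,Ala,Asp,Bip,Bip,8.5,FALSE,120.1,8.72,ala_scan,TRUE
RXL-3007,His,Aib,Glu,Gly,Thr,Phe(2-F),Thr,Ser,Ala,Bip,Bip,14.0,FALSE,131.6,8.32,ala_scan,TRUE
RXL-3008,His,Aib,Glu,Gly,Thr,Phe(2-F),Thr,Ser,Asp,Ala,Bip,NA,TRUE,43.6,6.37,ala_scan,TRUE
RXL-3009,His,Aib,Glu,Gly,Thr,Phe(2-F),Thr,Ser,Asp,Bip,Ala,NA,TRUE,43.2,6.00,ala_scan,TRUE
RXL-3030,Aib,Aib,Glu,Gly,Thr,aMe-Phe(2-F),Thr,Ser,Asp,Bip,Bip,1.3,FALSE,111.6,8.58,aib_scan,TRUE
RXL-3031,His,Aib,Aib,Gly,Thr,aMe-Phe(2-F),Thr,Ser,Asp,Bip,Bip,4.0,FALSE,121.3,8.31,aib_scan,TRUE
RXL-3032,His,Aib,Glu,Aib,Thr,aMe-Phe(2-F),Thr,Ser,Asp,Bip,Bip,14.2,FALSE,117.7,7.80,aib_scan,TRUE
RXL-3033,His,Aib,Glu,Gly,Aib,aMe-Phe(2-F),Thr,Ser,Asp,Bip,Bip,6.9,FALSE,119.9,8.13,aib_scan,TRUE
RXL-3028,His,Aib,Glu,Gly,Thr,Aib,Thr,Ser,Asp,Bip,Bip,161.0,FALSE,76.1,6.98,aib_scan,TRUE
RXL-3034,His,Aib,Glu,Gly,Thr,aMe-Phe(2-F),Aib,Ser,Asp,Bip,Bip,80.2,FALSE,105.7,7.04,aib_scan,TRUE
RXL-3035,His,Aib,Glu,Gly,Thr,aMe-Phe(2-F),Thr,Aib,Asp,Bip,Bip,111.0,FALSE,79.1,6.89,aib_scan,TRUE
RXL-3036,His,Aib,Glu,Gly,Thr,aMe-Phe(2-F),Thr,Ser,Aib,Bip,Bip,67.5,FALSE,96.7,7.04,aib_scan,TRUE
RXL-3051,His,Aib,Glu,Gly,Thr,aMe-Phe(2-F),Thr,Ser,Asp,Aib,Bip,NA,TRUE,26.8,6.00,aib_scan,TRUE
RXL-3052,His,Aib,Glu,Gly,Thr,aMe-Phe(2-F),Thr,Ser,Asp,Bip,Aib,7.4,FALSE,112.3,8.08,aib_scan,TRUE
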