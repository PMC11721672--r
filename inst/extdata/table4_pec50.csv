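position,aib_id,aib_pec50,ala_id,ala_pec50,dpec50_printed,role
6,RXL-101,10.89,RXL-3000,9.92,0.97,parent
1,RXL-3030,8.58,RXL-3001,7.86,-0.26,scan
2,RXL-101,10.89,RXL-3002,9.92,0.00,scan
3,RXL-3031,8.31,RXL-3003,8.47,-1.13,scan
4,RXL-3032,7.80,RXL-3037,6.46,0.37,scan
5,RXL-3033,8.13,RXL-3004,8.16,-1.00,scan
6,RXL-3028,6.98,RXL-3038,5.55,0.46,scan
7,RXL-3034,7.04,RXL-3005,7.67,-1.60,scan
8,RXL-3035,6.89,RXL-3006,8.72,-2.80,scan
9,RXL-3036,7.04,RXL-3007,8.32,-2.26,scan
10,RXL-3051,6.00,RXL-3008,6.37,-1.34,scan
11,RXL-3052,8.08,RXL-3009,6.00,1.11,scan
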