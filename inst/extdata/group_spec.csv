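name,task,metric,hd_mean,hd_sd,ld_mean,ld_sd,lower,upper,integer,printed_t,printed_p,printed_fdr,printed_d
"Task 1_P(2) Sad(FT,O)",1,FT,4.87,0.05,4.78,0.13,0,5,FALSE,-3.518,0.001,0.027,0.914
"Task 1_P(1) Neutral(SPL,O)",1,SPL,1470.45,720.71,1967.80,951.87,0,Inf,FALSE,2.243,0.029,0.047,0.589
"Task 1_P(1) Neutral(ASS,O)",1,ASS,326.83,195.61,454.61,274.80,0,Inf,FALSE,2.040,0.046,0.048,0.536
"Task 1_P(1) Neutral(ASS,F)",1,ASS,293.23,158.23,466.23,413.55,0,Inf,FALSE,2.104,0.042,0.047,0.553
"Task 1_P(2) Sad(ASS,E)",1,ASS,210.91,148.36,144.01,89.81,0,Inf,FALSE,-2.077,0.042,0.047,0.546
"Task 1_P(6) Sad(ASS,O)",1,ASS,351.96,198.86,509.62,359.65,0,Inf,FALSE,2.066,0.045,0.048,0.543
"Task 1_P(8) Angry(ASS,E)",1,ASS,256.32,183.21,165.90,100.15,0,Inf,FALSE,-2.332,0.023,0.047,0.612
"Task 2_P(4) Neutral_AT",2,AT,2.79,1.15,3.69,1.67,0,Inf,TRUE,2.383,0.021,0.047,0.628
"Task 2_P(4) Neutral_AL",2,AL,0.21,0.09,0.25,0.09,0,1,FALSE,2.002,0.049,0.049,0.444
"Task 3_P(5) Neutral(SPL,O)",3,SPL,1992.05,975.19,2683.48,1399.17,0,Inf,FALSE,2.183,0.033,0.047,0.573
"Task 3_P(5) Neutral(SPL,F)",3,SPL,1341.19,512.77,1751.21,772.15,0,Inf,FALSE,2.382,0.021,0.047,0.626
"Task 3_P(5) Neutral(SPL,EM)",3,SPL,1170.81,402.88,1466.49,649.83,0,Inf,FALSE,2.083,0.042,0.047,0.547
"Task 3_P(8) Angry(SPL,O)",3,SPL,1555.07,778.69,2094.67,1117.45,0,Inf,FALSE,2.133,0.037,0.047,0.560
"Task 3_P(9) Neutral(SPL,F)",3,SPL,1485.62,448.82,1855.47,816.40,0,Inf,FALSE,2.138,0.038,0.047,0.561
"Task 3_P(9) Neutral(SPL,EM)",3,SPL,1199.24,381.03,1464.16,542.22,0,Inf,FALSE,2.153,0.036,0.047,0.565
"Task 3_P(11) Happy(SPL,F)",3,SPL,1214.08,436.22,1583.37,742.26,0,Inf,FALSE,2.310,0.026,0.047,0.607
"Task 3_P(11) Happy(SPL,EM)",3,SPL,1019.00,369.23,1374.96,572.30,0,Inf,FALSE,2.814,0.007,0.027,0.739
"Task 3_P(5) Neutral(ASS,F)",3,ASS,319.89,134.10,437.50,265.85,0,Inf,FALSE,2.127,0.038,0.047,0.559
"Task 3_P(5) Neutral(ASS,EM)",3,ASS,276.07,88.59,390.67,181.63,0,Inf,FALSE,3.054,0.003,0.027,0.802
"Task 3_P(6) Neutral(ASS,F)",3,ASS,264.69,151.77,371.66,215.10,0,Inf,FALSE,2.188,0.033,0.047,0.575
"Task 4_P(2)16 Happy_FT",4,FT,0.28,0.27,0.46,0.35,0,10,FALSE,2.250,0.028,0.047,0.576
"Task 4_P(4)3 Sad_FT",4,FT,0.99,0.66,0.56,0.41,0,10,FALSE,-3.023,0.004,0.027,0.783
"Task 4_P(4)12 Happy_FT",4,FT,0.18,0.22,0.39,0.33,0,10,FALSE,2.833,0.006,0.027,0.749
"Task 4_P(4) Neutral_AL",4,AL,0.39,0.12,0.45,0.10,0,1,FALSE,2.292,0.026,0.047,0.608
"Task 4_P(2)16 Happy_AL",4,AL,0.03,0.03,0.05,0.04,0,1,FALSE,2.279,0.026,0.047,0.566
"Task 4_P(4)12 Happy_AL",4,AL,0.02,0.02,0.04,0.03,0,1,FALSE,2.823,0.007,0.027,0.784
"Task 4_P(4)3 Sad_AL",4,AL,0.10,0.07,0.06,0.04,0,1,FALSE,-3.042,0.004,0.027,0.702
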