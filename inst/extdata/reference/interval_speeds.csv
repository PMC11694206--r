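position,offset_s,mean_kmh,sd_kmh,n
CD,-10,5.11,3.60,20
CD,-9,5.53,4.34,20
CD,-8,7.07,5.08,20
CD,-7,8.18,5.10,20
CD,-6,9.35,5.95,20
CD,-5,11.99,5.69,20
CD,-4,14.59,7.21,20
CD,-3,18.02,6.54,20
CD,-2,22.48,5.50,20
CD,-1,25.75,5.08,20
CD,0,29.11,1.64,20
CD,1,25.34,5.61,20
CD,2,20.14,6.55,20
CD,3,14.91,7.63,20
CD,4,12.55,7.19,20
CD,5,11.07,6.11,20
CD,6,8.74,5.84,20
CD,7,7.63,5.50,20
CD,8,7.59,5.41,20
CD,9,7.47,5.09,20
CD,10,7.34,4.62,20
FB,-10,7.40,4.09,10
FB,-9,8.78,6.02,10
FB,-8,10.03,7.58,10
FB,-7,11.24,7.65,10
FB,-6,13.08,8.57,10
FB,-5,15.07,9.04,10
FB,-4,18.93,7.86,10
FB,-3,22.53,5.32,10
FB,-2,26.57,3.80,10
FB,-1,29.29,3.15,10
FB,0,31.64,1.94,10
FB,1,27.83,4.97,10
FB,2,20.85,8.14,10
FB,3,13.74,7.92,10
FB,4,11.56,6.55,10
FB,5,11.37,5.72,10
FB,6,10.66,4.26,10
FB,7,8.83,5.40,10
FB,8,7.92,5.69,10
FB,9,7.65,6.19,10
FB,10,7.45,6.31,10
CM,-10,8.02,4.94,19
CM,-9,8.54,4.89,19
CM,-8,9.37,4.71,19
CM,-7,10.39,5.15,19
CM,-6,12.59,5.12,19
CM,-5,16.69,4.70,19
CM,-4,18.49,5.10,19
CM,-3,21.20,5.19,19
CM,-2,24.54,4.08,19
CM,-1,27.43,2.95,19
CM,0,30.26,2.23,19
CM,1,27.68,3.08,19
CM,2,21.97,6.63,19
CM,3,15.05,7.54,19
CM,4,12.27,6.72,19
CM,5,9.80,6.00,19
CM,6,9.51,5.11,19
CM,7,9.15,4.60,19
CM,8,7.88,4.24,19
CM,9,6.90,4.11,19
CM,10,6.58,4.23,19
WM,-10,8.30,5.43,24
WM,-9,8.42,6.87,24
WM,-8,9.18,6.94,24
WM,-7,9.47,6.19,24
WM,-6,10.05,6.30,24
WM,-5,12.28,6.66,24
WM,-4,16.40,6.45,24
WM,-3,21.48,4.97,24
WM,-2,25.43,3.27,24
WM,-1,28.67,2.46,24
WM,0,30.68,2.61,24
WM,1,26.82,5.47,24
WM,2,19.12,8.91,24
WM,3,13.23,9.56,24
WM,4,10.46,8.94,24
WM,5,10.13,8.20,24
WM,6,9.91,6.60,24
WM,7,9.40,5.66,24
WM,8,8.39,5.38,24
WM,9,7.46,5.75,24
WM,10,7.01,5.11,24
FW,-10,9.21,6.84,17
FW,-9,7.96,5.34,17
FW,-8,8.88,5.39,17
FW,-7,8.99,5.18,17
FW,-6,8.78,5.10,17
FW,-5,9.45,5.55,17
FW,-4,12.70,5.83,17
FW,-3,18.85,4.59,17
FW,-2,24.03,2.74,17
FW,-1,27.38,2.39,17
FW,0,29.83,1.88,17
FW,1,26.72,3.62,17
FW,2,20.02,7.14,17
FW,3,14.78,6.78,17
FW,4,10.77,5.21,17
FW,5,9.39,5.22,17
FW,6,8.74,5.13,17
FW,7,8.28,4.48,17
FW,8,7.71,3.56,17
FW,9,7.41,3.61,17
FW,10,6.55,3.01,17
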