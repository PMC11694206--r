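pos1,pos2,mean_diff,diff_lo,diff_hi,d,d_lo,d_hi,magnitude
CD,FB,2.50,1.12,3.88,1.40,0.63,2.40,large
CD,CM,1.13,-0.14,2.39,0.57,-0.06,1.26,unclear
CD,WM,1.55,0.19,2.93,0.69,0.09,1.35,moderate
CD,FW,0.69,-0.48,1.87,0.39,-0.26,1.09,unclear
FB,CM,-1.38,-3.09,0.34,-0.62,-1.50,0.14,unclear
FB,WM,-0.95,-2.82,0.92,-0.38,-1.18,0.37,unclear
FB,FW,-1.81,-3.37,-0.25,-0.92,-1.87,-0.14,moderate
CM,WM,0.42,-1.10,1.95,0.17,-0.44,0.80,unclear
CM,FW,-0.44,-1.84,0.97,-0.21,-0.90,0.46,unclear
WM,FW,-0.86,-2.36,0.64,-0.36,-1.03,0.27,unclear
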