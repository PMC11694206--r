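pair,phase,mean_diff,diff_lo,diff_hi,d,d_lo,d_hi,magnitude
10-9,pre,0.15,-0.10,0.40,0.03,-0.02,0.07,unclear
9-8,pre,1.03,0.83,1.24,0.18,0.14,0.21,trivial
8-7,pre,0.69,0.46,0.93,0.12,0.08,0.16,trivial
7-6,pre,1.04,0.76,1.32,0.17,0.13,0.22,trivial
6-5,pre,2.40,2.12,2.67,0.37,0.33,0.41,small
5-4,pre,3.10,2.80,3.40,0.46,0.41,0.51,small
4-3,pre,4.25,3.99,4.52,0.68,0.64,0.73,moderate
3-2,pre,4.18,3.97,4.38,0.84,0.80,0.88,moderate
2-1,pre,3.13,2.99,3.28,0.80,0.76,0.85,moderate
1-2,post,-6.55,-6.89,-6.21,-1.04,-1.10,-0.98,moderate
2-3,post,-5.72,-6.02,-5.41,-0.73,-0.78,-0.68,moderate
3-4,post,-2.93,-3.24,-2.62,-0.38,-0.42,-0.34,small
4-5,post,-1.06,-1.31,-0.81,-0.15,-0.19,-0.12,trivial
5-6,post,-0.95,-1.17,-0.73,-0.16,-0.19,-0.12,trivial
6-7,post,-0.97,-1.17,-0.76,-0.18,-0.22,-0.14,trivial
7-8,post,-0.65,-0.84,-0.47,-0.13,-0.17,-0.09,trivial
8-9,post,-0.43,-0.59,-0.27,-0.09,-0.12,-0.06,trivial
9-10,post,-0.37,-0.51,-0.24,-0.08,-0.11,-0.05,trivial
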