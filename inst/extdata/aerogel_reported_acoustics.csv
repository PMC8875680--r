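name,v_m_s,Z_Mrayl,mismatch_pct
X-silica,80.58,0.104,92.03
X-silica-La2O2S:Eu,90.21,0.126,90.28
X-Ca-Alg-1,48.80,0.026,97.97
X-Ca-Alg-2,42.48,0.026,98.03
BRF-CA,25.74,0.038,97.16
ARF-CA,28.83,0.040,97.12
SMPU-Mix-18,17.41,0.025,98.23
SMPU-Mix-14,14.75,0.022,98.33
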