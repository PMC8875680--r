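name,alpha_Aq_db_cm,sem_Aq,alpha_SM_db_cm,sem_SM,alpha_SC_db_cm,sem_SC
X-silica-La2O2S:Eu,8.21,0.14,13.76,1.15,20.84,0.14
X-silica,7.13,0.15,9.80,0.38,14.24,0.98
SMPU-Mix-18,6.53,0.01,9.12,0.17,13.80,0.07
SMPU-Mix-14,4.30,0.88,5.96,0.55,8.06,0.70
X-Ca-Alg-2,3.54,0.09,7.46,0.39,10.54,0.08
X-Ca-Alg-1,3.11,0.12,7.42,0.21,9.41,0.35
BRF-CA,2.68,0.35,6.60,0.67,4.61,0.16
ARF-CA,2.39,0.44,4.77,0.46,3.27,0.05
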