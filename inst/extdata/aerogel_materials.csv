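name,Y_MPa,Y_err_MPa,rho_kg_m3,phi_um,phi_err_um,porosity
X-silica,8.35,2.68,729.48,0.10,0.012,NA
X-silica-La2O2S:Eu,11.40,2.20,939.20,0.13,0.01,NA
X-Ca-Alg-1,1.30,0.20,88.76,0.19,0.01,NA
X-Ca-Alg-2,1.09,0.02,150.49,0.18,0.01,NA
BRF-CA,0.95,0.10,883.06,0.04,0.001,NA
ARF-CA,0.91,0.09,826.62,5.00,0.17,NA
SMPU-Mix-18,0.40,0.07,672.07,2.05,0.19,NA
SMPU-Mix-14,0.32,0.07,637.01,2.67,0.16,NA
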