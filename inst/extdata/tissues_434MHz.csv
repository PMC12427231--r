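name,eps_r,sigma_S_per_m,rho_kg_per_m3,k_W_per_mC,cp_J_per_kgC,omega_ml_per_min_kg
skin,46.1,0.70,1109,0.37,3391,106
fat,11.6,0.08,911,0.21,2348,33
muscle,56.9,0.81,1090,0.49,3421,39
bone,13.1,0.09,1908,0.32,1313,10
spinal_cord,35.4,0.46,1075,0.51,3630,160
tumor,59,0.89,1050,0.51,3421,72
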