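# Limiting ionic mobilities u (m^2 V^-1 s^-1), derived from limiting molar
# conductivities at 25 C (CRC Handbook of Chemistry and Physics, 95th ed.,
# "Ionic conductivity and diffusion at infinite dilution") via u = Lambda/(|z| F).
# Edit or extend this file to override the shipped values.
name	z	u
H+	1	3.623e-07
K+	1	7.62e-08
Na+	1	5.19e-08
NH4+	1	7.62e-08
Ca2+	2	6.17e-08
Mg2+	2	5.49e-08
Cl-	-1	7.91e-08
NO3-	-1	7.40e-08
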