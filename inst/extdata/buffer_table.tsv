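# pH buffers for proton-flux correction. pK at 25 C. D_HA (m^2 s^-1) is the
# handbook diffusion coefficient of the protonated (neutral-acid) form;
# u_HA = D_HA / 0.0251887 V so buffer and ion transport share one Einstein
# voltage. polyprotic = 1 marks organic acids with several pK_A values, usable
# only when the solution pH is within 0.25 units of the tabulated pK.
name	pK	u_HA	D_HA	polyprotic
Mes	6.1	2.501e-08	6.3e-10	0
TRIS	8.1	3.017e-08	7.6e-10	0
citrate	4.76	2.620e-08	6.6e-10	1
malate	5.11	2.779e-08	7.0e-10	1
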