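parameter,unit,x_min,x_max,description
Lr,Pa-1.s-1,5e-9,5e-6,Normalized hydraulic conductivity of the plasma membrane (2L/r)
mu,m3.Pa-1.s-1,1.35e-26,3.3e-19,Total plasmodesmal permeability for open plasmodesmata
alpha,Pa.s-1,8.3e1,1.67e2,Normalized solute source rate (uptake/synthesis)
pi_seed,Pa,9.9e5,1.29e6,Osmotic pressure of the seed proper
P_seed,Pa,7e4,1.8e5,Turgor pressure of the seed
Y,Pa,6e4,2e5,Yield turgor threshold for irreversible wall expansion
phi,Pa-1.s-1,1.1e-12,2.5e-11,Cell wall extensibility (inverse effective wall viscosity)
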