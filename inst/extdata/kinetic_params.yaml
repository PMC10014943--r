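# Default kinetic parameter set for the Rac-Rho-paxillin models (6V / 2V / 4V).
# Fast-subsystem constants follow the published Rac-Rho-paxillin model lineage;
# the slow-timescale constants were calibrated once against the reported regime
# structure of the four-variable model (see the methods vignette).
# All rates are per unit time; concentrations are scaled (dimensionless unless
# noted); diffusion coefficients are length^2 / time.
"n": 4          # Hill coefficient (bare n is YAML 1.1 boolean, keep quoted)
L_rho: 0.34     # Rho-dependent half-maximum inhibition of Rac
L_R: 0.34       # Rac-dependent half-maximum inhibition of Rho
L_K: 5.77       # half-maximum phosphorylation of paxillin w.r.t. active PAK
I_R: 0.0005     # basal Rac activation rate
I_rho: 0.016    # Rho activation rate
I_K: 0.035      # maximum GIT-PIX-PAK-dependent Rac activation rate
delta_R: 0.04   # Rac inactivation rate
delta_rho: 0.016  # Rho inactivation rate
delta_P: 0.000415  # paxillin dephosphorylation rate
gamma: 0.3      # ratio of total PAK to total Rac
alpha_P: 0.3    # linearization coefficient, total vs phosphorylated paxillin
alpha_R: 15     # PAK-RacGTP affinity constant
k_X: 41.7       # association constant, PIX-PAK
k_G: 5.71       # association constant, GIT-PIX
k_C: 5          # association constant, phosphopaxillin-GIT
GIT: 0.11       # GIT concentration
PIX: 0.02       # PIX concentration
Pax_tot: 2.3    # total paxillin concentration
B: 4            # maximum paxillin phosphorylation rate (2V/6V; state in 4V)
eps: 0.01       # slow timescale of B
eps_L: 0.00022222222222222223  # very slow timescale of k_B (eps / 45)
eps_B: 0.1      # barrier offset in the B equation
eta: 3          # barrier strength in the B equation
B_r: 10         # resting state of B
gamma_R: 5      # strength of slow negative feedback of R on B
gamma_K: 0.26   # target Rac level of the k_B recovery dynamics
D_R: 0.1        # diffusion, active Rac
D_Ri: 10        # diffusion, inactive Rac
D_rho: 0.1      # diffusion, active Rho (6V)
D_rhoi: 10      # diffusion, inactive Rho (6V)
D_P: 0.1        # diffusion, phosphorylated paxillin (6V)
D_Pi: 10        # diffusion, unphosphorylated paxillin (6V)
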