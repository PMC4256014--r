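# sacwave parameter registry
# units: voltages mV, conductances nS, times s, concentrations nM,
#        capacitance nF, diffusion mm^2/s, rates 1/s, lengths mm
membrane_capacitance: 0.16
# reversal potentials (mV)
reversal_potentials.E_K: -90
reversal_potentials.E_Ca: 50
reversal_potentials.E_leak: -70
reversal_potentials.E_ACh: 50
# maximal conductances (nS)
max_conductances.g_leak: 2
max_conductances.g_K: 10
max_conductances.g_Ca: 30
max_conductances.g_ACh: 3
max_conductances.g_noise: 2
# Morris-Lecar gating constants (mV; tau_w s)
gating_params.m_half: -20
gating_params.m_slope: 20
gating_params.w_half: -40
gating_params.w_slope: 40
gating_params.tau_w: 0.20000000000000001
# sAHP cascade (mV; s; strength dimensionless)
sahp_params.half: -25
sahp_params.slope: 5
sahp_times.tau_R: 5
sahp_times.tau_S: 60
sahp_strength: 5
# ACh release, clearance and receptor (mV; nM/s; s; nM)
ach_params.release_half: -55
ach_params.release_slope: 5
ach_params.release_rate: 20000
ach_params.clearance_time: 0.20000000000000001
ach_params.half_saturation: 800
ach_params.hill_coefficient: 2
# effective ACh diffusion (mm^2/s)
diffusion_coefficient: 0.01
# stochastic excitatory channel
noise.open_probability_rate: 0.12
noise.update_interval: 0.01
# domain
domain.length: 2
domain.grid_n: 64
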