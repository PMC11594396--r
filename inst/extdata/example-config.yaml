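# Example netcoop configuration. Every key is optional; omitted keys take
# the study defaults (b = 9, c = 8, delta = 0.01, mu_c = -0.5, mu_d = 0.5,
# sigma2 = 0.5, rc = 0.8, n = 100, init_density = 0.30, burn_in = 10000).
n: 100
init_density: 0.30
burn_in: 10000
max_steps: 1000000
method: BET_LO       # DEG_HI DEG_LO BET_HI BET_LO EIG_HI EIG_LO RANDOM
tau: 1.6
p: 0.25
q: 0.25
seed: 1
# sweep grids (used by the `sweep` subcommand)
tau_grid: [-2.0, -1.0, 0.0, 1.0, 1.6, 2.0]
methods: [DEG_HI, DEG_LO, BET_HI, BET_LO, EIG_HI, EIG_LO, RANDOM]
pq_regimes: [[0.25, 0.25], [0.25, 0.75], [0.75, 0.25], [0.75, 0.75]]
n_trials: 1000
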