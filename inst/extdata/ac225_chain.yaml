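# Default Ac-225 decay-chain constants.
# Half-lives: Ac-225 9.9 d, Fr-221 4.8 min, At-217 32 ms, Bi-213 45.6 min
# (Po-213 3.72 us from standard nuclear data; it is too short-lived to matter
# kinetically but carries most of the Bi-213 branch alpha energy).
# alpha_yield is the number of alpha emissions of that nuclide per Ac-225
# chain decay under secular equilibrium: Bi-213 alpha-decays in 2.1% of
# decays (the remaining 97.9% beta-decay to Po-213, which alpha-decays).
# Per primary alpha this is 25% / 25% / 25% / 0.52% / 24.48%.
# alpha_energy_MeV are standard nuclear-data values (overridable).
nuclides:
  - name: Ac-225
    half_life: 9.9 d
    alpha_energy_MeV: 5.830
    alpha_yield: 1.0
  - name: Fr-221
    half_life: 4.8 min
    alpha_energy_MeV: 6.341
    alpha_yield: 1.0
  - name: At-217
    half_life: 32 ms
    alpha_energy_MeV: 7.067
    alpha_yield: 1.0
  - name: Bi-213
    half_life: 45.6 min
    alpha_energy_MeV: 5.875
    alpha_yield: 0.021
  - name: Po-213
    half_life: 3.72 us
    alpha_energy_MeV: 8.376
    alpha_yield: 0.979
parent: Ac-225
daughter: Bi-213
alphas_per_chain: 4
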