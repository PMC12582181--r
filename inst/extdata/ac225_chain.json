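{
  "comment": [
    "Actinium-225 decay chain with branching-weighted mean alpha energies.",
    "Values are intensity-weighted mean alpha-particle energies (MeV) per",
    "decay of each chain member, compiled from standard evaluated nuclear",
    "data (ENSDF / NNDC Nuclear Wallet Cards, A=209..225 evaluations).",
    "branching_fraction is the probability that one parent (Ac-225) decay",
    "passes through the step; alternative branches share a 'position' and",
    "their fractions sum to 1. Beta/gamma emissions carry no alpha energy",
    "and are listed with mean_alpha_energy_mev = 0.",
    "Total branching-weighted alpha energy: 27.48 MeV per Ac-225 decay."
  ],
  "parent": { "name": "Ac-225", "half_life": 9.92, "unit": "d" },
  "steps": [
    { "nuclide": "Ac-225", "position": 1, "branching_fraction": 1.0,
      "mean_alpha_energy_mev": 5.790, "mode": "alpha" },
    { "nuclide": "Fr-221", "position": 2, "branching_fraction": 1.0,
      "mean_alpha_energy_mev": 6.303, "mode": "alpha" },
    { "nuclide": "At-217", "position": 3, "branching_fraction": 1.0,
      "mean_alpha_energy_mev": 7.067, "mode": "alpha" },
    { "nuclide": "Bi-213", "position": 4, "branching_fraction": 0.978,
      "mean_alpha_energy_mev": 0.0, "mode": "beta" },
    { "nuclide": "Bi-213", "position": 4, "branching_fraction": 0.022,
      "mean_alpha_energy_mev": 5.870, "mode": "alpha" },
    { "nuclide": "Po-213", "position": 5, "branching_fraction": 0.978,
      "mean_alpha_energy_mev": 8.376, "mode": "alpha" },
    { "nuclide": "Tl-209", "position": 5, "branching_fraction": 0.022,
      "mean_alpha_energy_mev": 0.0, "mode": "beta" },
    { "nuclide": "Pb-209", "position": 6, "branching_fraction": 1.0,
      "mean_alpha_energy_mev": 0.0, "mode": "beta" }
  ],
  "terminal": { "nuclide": "Bi-209", "stable": true }
}
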