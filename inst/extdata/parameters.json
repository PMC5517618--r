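{
  "comment": "Mouse ventricular myocyte model constants (apical cell). Units: ms, mV, pA/pF, uM; volumes in uL, Acap in cm2, F in C/mmol, T in K. The 'tg' block lists the seven parameters remodeled in the TNF-alpha overexpressing (heart-failure) myocyte; all other constants are shared. TG values are a literature-informed reconstruction of the reported TNF-alpha remodeling (reduced I_Kto,f, I_Kur and I_K1, upregulated Na/Ca exchange, reduced SERCA uptake).",
  "wt": {
    "Acap": 1.534e-4, "Cm": 1.0,
    "Vmyo": 25.84e-6, "VJSR": 0.12e-6, "VNSR": 2.098e-6, "Vss": 1.485e-9,
    "Ko": 5400, "Nao": 140000, "Cao": 1800,
    "F": 96.5, "TK": 298, "Rgas": 8.314,
    "v1": 4.5, "v2": 1.74e-5, "v3": 0.45, "Km_up": 0.5,
    "tau_tr": 20, "tau_xfer": 8,
    "ka_plus": 0.006075, "ka_minus": 0.07125,
    "kb_plus": 0.00405, "kb_minus": 0.965,
    "kc_plus": 0.009, "kc_minus": 0.0008,
    "n_ryr": 4, "m_ryr": 3,
    "LTRPN_tot": 70, "HTRPN_tot": 140,
    "k_htrpn_plus": 0.00237, "k_htrpn_minus": 3.2e-5,
    "k_ltrpn_plus": 0.0327, "k_ltrpn_minus": 0.0196,
    "CMDN_tot": 50, "Km_CMDN": 0.238,
    "CSQN_tot": 15000, "Km_CSQN": 800,
    "GCaL": 0.1729, "ECaL": 63, "Kpc_max": 0.23324, "Kpc_half": 20,
    "Kpcb": 0.0005, "ICaL_max": 7,
    "GNa": 13, "GNab": 0.0026, "GCab": 0.000367,
    "kNaCa": 292.8, "Km_Na": 87500, "Km_Ca": 1380, "k_sat": 0.1, "eta": 0.35,
    "IpCa_max": 1.0, "Km_pCa": 0.5,
    "INaK_max": 0.88, "Km_Nai": 21000, "Km_Ko": 1500,
    "GKtof": 0.4067, "GKtos": 0.0, "GKur": 0.16, "GKss": 0.0503,
    "GKs": 0.00575, "GKr": 0.078, "kf": 0.023761, "kb": 0.036778,
    "GK1": 0.2938, "K1_half": 210, "nK1": 1, "sK1": 0.0896,
    "GClCa": 10, "Km_Cl": 10, "ECl": -40
  },
  "tg": {
    "v3": 0.306,
    "kNaCa": 527.04,
    "GKtof": 0.2644,
    "GKur": 0.096,
    "GK1": 0.2203,
    "nK1": 2,
    "sK1": 0.112
  },
  "flagged": ["v3", "kNaCa", "GKtof", "GKur", "GK1", "nK1", "sK1"],
  "ina_scheme": {
    "states_full": ["CNa3", "CNa2", "CNa1", "ONa", "IFNa", "I1Na", "I2Na", "ICNa2", "ICNa3"],
    "states_no_slow_inact": ["CNa3", "CNa2", "CNa1", "ONa", "IFNa", "ICNa2", "ICNa3"],
    "edges": [
      {"from": "CNa3",  "to": "CNa2",  "rate": "alpha_Na11"},
      {"from": "CNa2",  "to": "CNa3",  "rate": "beta_Na11"},
      {"from": "CNa2",  "to": "CNa1",  "rate": "alpha_Na12"},
      {"from": "CNa1",  "to": "CNa2",  "rate": "beta_Na12"},
      {"from": "CNa1",  "to": "ONa",   "rate": "alpha_Na13"},
      {"from": "ONa",   "to": "CNa1",  "rate": "beta_Na13"},
      {"from": "ONa",   "to": "IFNa",  "rate": "alpha_Na2"},
      {"from": "IFNa",  "to": "ONa",   "rate": "beta_Na2"},
      {"from": "CNa1",  "to": "IFNa",  "rate": "beta_Na3"},
      {"from": "IFNa",  "to": "CNa1",  "rate": "alpha_Na3"},
      {"from": "IFNa",  "to": "I1Na",  "rate": "alpha_Na4"},
      {"from": "I1Na",  "to": "IFNa",  "rate": "beta_Na4"},
      {"from": "I1Na",  "to": "I2Na",  "rate": "alpha_Na5"},
      {"from": "I2Na",  "to": "I1Na",  "rate": "beta_Na5"},
      {"from": "CNa2",  "to": "ICNa2", "rate": "beta_Na3"},
      {"from": "ICNa2", "to": "CNa2",  "rate": "alpha_Na3"},
      {"from": "CNa3",  "to": "ICNa3", "rate": "beta_Na3"},
      {"from": "ICNa3", "to": "CNa3",  "rate": "alpha_Na3"},
      {"from": "ICNa2", "to": "IFNa",  "rate": "alpha_Na12"},
      {"from": "IFNa",  "to": "ICNa2", "rate": "beta_Na12"},
      {"from": "ICNa3", "to": "ICNa2", "rate": "alpha_Na11"},
      {"from": "ICNa2", "to": "ICNa3", "rate": "beta_Na11"}
    ]
  }
}
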