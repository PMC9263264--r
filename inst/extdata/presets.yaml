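# Named parameter presets for the two-population noise-driven random network.
# Fractions may be written as strings ("1/3") and are parsed exactly.
fig2a:
  N_E: 1500
  N_I: 1000
  m_EE: 1
  m_IE: 0.75
  m_EI: -0.25
  m_II: -0.5
  g: 1.4
  sigma: 0.8
  eta_E: "1/3"
  eta_I: "1/2"
  transfer: atan
fig2b:
  N_E: 1500
  N_I: 1000
  m_EE: 1
  m_IE: 0.75
  m_EI: -0.25
  m_II: -0.5
  g: 1.4
  sigma: 0.8
  eta_E: "1/3"
  eta_I: 0
  transfer: atan
fig2c:
  N_E: 1500
  N_I: 1000
  m_EE: 1
  m_IE: 75
  m_EI: -0.25
  m_II: -50
  g: 1.4
  sigma: 0.8
  eta_E: "1/3"
  eta_I: "1/2"
  transfer: relu_atan
fig2d:
  N_E: 1500
  N_I: 1000
  m_EE: 1
  m_IE: 75
  m_EI: -0.25
  m_II: -50
  g: 1.4
  sigma: 0.8
  eta_E: 0
  eta_I: 0
  transfer: relu_atan
fig3a:
  N_E: 1500
  N_I: 1000
  m_EE: 1
  m_IE: 0.75
  m_EI: -0.25
  m_II: -0.5
  g: 1.4
  sigma: 0.8
  eta_E: "1/3"
  eta_I: "1/2"
  transfer: atan
fig3b:
  N_E: 1500
  N_I: 1000
  m_EE: 1
  m_IE: 0.75
  m_EI: -0.25
  m_II: -0.5
  g: 1.4
  sigma: 0.8
  eta_E: -1
  eta_I: 0.5
  transfer: atan
fig3c:
  N_E: 1500
  N_I: 1000
  m_EE: 1
  m_IE: 0.75
  m_EI: -25
  m_II: -50
  g: 1.4
  sigma: 0.8
  eta_E: "1/3"
  eta_I: "1/2"
  transfer: relu_atan
fig4:
  N_E: 1500
  N_I: 1000
  m_EE: 1
  m_IE: 0.75
  m_EI: -0.25
  m_II: -0.5
  g: 3
  sigma: 0.8
  eta_E: -1
  eta_I: 0.5
  transfer: atan
fig9:
  N_E: 1500
  N_I: 1000
  m_EE: 1
  m_IE: 0.75
  m_EI: -0.25
  m_II: -0.5
  g: 1.3
  sigma: 0.8
  eta_E: -1
  eta_I: 0.5
  transfer: atan
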