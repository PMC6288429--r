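# PKA phosphorylation effects per target population.
# Each entry: the multiplicative modification applied to the phosphorylated
# population of that target, and the source the magnitude was adapted from.
# These constants are data: edit and pass the file to phospho_effects()
# to change them without touching code.
targets:
  LTCC:
    amp: 2.5
    description: unitary current amplification of a PKA-phosphorylated LTCC
    citation: Heijman et al. 2011 J Mol Cell Cardiol 50:863-871
  RyR:
    amp: 1.75
    description: SR release flux amplification (higher open probability)
    citation: adapted from Heijman et al. 2011 beta-adrenergic model
  PLB:
    km_up_factor: 0.5
    description: SERCA Ca affinity doubled (phospholamban inhibition relieved)
    citation: adapted from Heijman et al. 2011 beta-adrenergic model
  IKs:
    amp: 2.0
    description: slow delayed-rectifier conductance increase
    citation: adapted from Heijman et al. 2011 beta-adrenergic model
  INa:
    amp: 1.25
    description: fast Na+ conductance increase
    citation: adapted from Heijman et al. 2011 beta-adrenergic model
  INaK:
    amp: 1.1
    description: Na+/K+ ATPase turnover increase
    citation: adapted from Heijman et al. 2011 beta-adrenergic model
  IKur:
    amp: 1.0
    maps_to: IKb
    description: >
      plateau K+ current increase; the human ventricular baseline model has
      no explicit IKur, so the effect is applied to the background K+
      current IKb, its conventional surrogate in this formulation
    citation: adapted from Heijman et al. 2011 beta-adrenergic model
  TnI:
    km_trpn_factor: 1.6
    description: troponin Ca affinity reduced (faster myofilament off-rate)
    citation: adapted from Heijman et al. 2011 beta-adrenergic model
  INaL:
    amp: 1.0
    description: CaMKII-only target; PKA phosphorylation leaves it unchanged
    citation: model assumption
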