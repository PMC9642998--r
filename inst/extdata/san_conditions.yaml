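# Autonomic condition transforms for the mouse SAN pacemaker cell model.
#
# scale: multiplicative effects on baseline parameter values
# shift: additive activation shifts, mV
# kach_dose_uM: agonist dose engaging the acetylcholine-activated K+ current
#
# ISO emulates beta-adrenergic stimulation: up-modulation of the L-type Ca2+
# current and SR uptake, a negative shift of ICaL/ICaT activation voltage
# (encoded as a positive ca_shift, which moves activation to more negative
# potentials) and a depolarizing shift of funny-current activation.
# CCh emulates muscarinic stimulation: IKACh activation at the 0.3 uM ex vivo
# superfusion dose plus a small hyperpolarizing funny-current shift.
conditions:
  baseline: {}
  iso:
    scale:
      G_CaL: 1.3
      G_Ks: 1.2
      v_up: 1.4
    shift:
      ca_shift: 5
      y_shift: 7
  cch:
    kach_dose_uM: 0.3
    shift:
      y_shift: -4
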