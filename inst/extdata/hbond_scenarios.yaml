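# Synthetic two-state contact kinetics for the two ligand protonation
# scenarios. Stationary bound fraction = (1-p_stay_unbound) /
# ((1-p_stay_bound) + (1-p_stay_unbound)). Distances in angstrom.
#
# protonated: persistent hinge hydrogen bonds (Glu121 backbone carbonyl,
#   Val123 amide H), no Lys72/Thr183 contact.
# deprotonated: carboxylate rotated away from the hinge; stable Lys72
#   side-chain contact, intermittent Thr183 hydroxyl contact that breaks and
#   reforms, no hinge contacts.
protonated:
  Glu121: {p_stay_bound: 0.999, p_stay_unbound: 0.980, bound_mean: 2.9, unbound_mean: 6.0, jitter_sd: 0.2}   # ~0.95
  Lys72:  {p_stay_bound: 0.900, p_stay_unbound: 0.998, bound_mean: 2.9, unbound_mean: 6.0, jitter_sd: 0.2}   # ~0.02
  Val123: {p_stay_bound: 0.999, p_stay_unbound: 0.980, bound_mean: 2.9, unbound_mean: 6.0, jitter_sd: 0.2}   # ~0.95
  Thr183: {p_stay_bound: 0.900, p_stay_unbound: 0.998, bound_mean: 2.9, unbound_mean: 6.0, jitter_sd: 0.2}   # ~0.02
deprotonated:
  Glu121: {p_stay_bound: 0.900, p_stay_unbound: 0.998, bound_mean: 2.9, unbound_mean: 6.0, jitter_sd: 0.2}   # ~0.02
  Lys72:  {p_stay_bound: 0.999, p_stay_unbound: 0.991, bound_mean: 2.9, unbound_mean: 6.0, jitter_sd: 0.2}   # ~0.90
  Val123: {p_stay_bound: 0.900, p_stay_unbound: 0.998, bound_mean: 2.9, unbound_mean: 6.0, jitter_sd: 0.2}   # ~0.02
  Thr183: {p_stay_bound: 0.995, p_stay_unbound: 0.995, bound_mean: 2.9, unbound_mean: 6.0, jitter_sd: 0.2}   # ~0.50, breaks/reforms
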