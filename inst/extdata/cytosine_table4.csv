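label,electronic_energy_hartree,zpe_hartree,multiplicity,role
(T)C1_NH+H,-393.6885329,0.089094,triplet,radical_asymptote
(S)C1_NH+H,-393.6886903,0.089094,singlet,radical_asymptote
(T)C2+H,-393.6910554,0.089393,triplet,radical_asymptote
(S)C2+H,-393.6916239,0.089393,singlet,radical_asymptote
C3,-393.8455581,0.104452,singlet,tautomer
C4,-393.8559784,0.104656,singlet,tautomer
C1,-393.8563302,0.104618,singlet,tautomer
C2,-393.8605199,0.104493,singlet,tautomer
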