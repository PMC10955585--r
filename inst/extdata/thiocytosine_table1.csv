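label,electronic_energy_hartree,zpe_hartree,multiplicity,role
(T)TC1_NH+H,-716.287852,0.087516,triplet,radical_asymptote
(S)TC1_NH+H,-716.288574,0.087516,singlet,radical_asymptote
(T)TC2+H,-716.316946,0.088322,triplet,radical_asymptote
(S)TC2+H,-716.317692,0.088322,singlet,radical_asymptote
TC3,-716.438030,0.102006,singlet,tautomer
TC4,-716.447750,0.102496,singlet,tautomer
TC1,-716.449542,0.102291,singlet,tautomer
TC2,-716.453817,0.098170,singlet,tautomer
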