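# Valence-state ionization potentials and electron affinities (eV) for
# 2p pi orbitals, Hinze-Jaffe style atom-in-molecule values.
# sigma_neighbors counts all bonded atoms including hydrogen.
# n_pi is the number of electrons the center donates to the pi system.
# table_version: 1
key,element,sigma_neighbors,n_pi,ip_ev,ea_ev
C.sp2,C,3,1,11.16,0.03
C.sp,C,2,1,11.16,0.03
N.pyridine,N,2,1,14.12,1.78
N.pyrrole,N,3,2,28.72,11.96
O.carbonyl,O,1,1,17.70,2.47
O.ether,O,2,2,34.12,15.30
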