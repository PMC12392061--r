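set	mirna
fpp_in_up	hsa-miR-218-5p
fpp_in_up	hsa-miR-335-5p
fpp_in_up	hsa-miR-137
fpp_in_up	hsa-let-7b-5p
fpp_in_up	hsa-miR-99b-5p
fpp_in_exclusive	hsa-miR-885-5p
fpp_in_exclusive	hsa-miR-642a-5p
nsc_in_up	hsa-miR-219a-2-3p
fpp_ev_up	hsa-let-7b-5p
fpp_ev_up	hsa-miR-137
fpp_ev_up	hsa-miR-218-5p
fpp_ev_up	hsa-miR-335-5p
fpp_ev_up	hsa-miR-99b-5p
fpp_ev_up	hsa-miR-885-5p
fpp_ev_up	hsa-miR-21-5p
fpp_ev_up	hsa-miR-26a-5p
fpp_ev_up	hsa-miR-24-3p
fpp_ev_up	hsa-miR-9-5p
fpp_ev_up	hsa-miR-1226-5p
nsc_ev_up	hsa-miR-219a-2-3p
nsc_ev_up	hsa-miR-217
nsc_ev_up	hsa-miR-216a-5p
nsc_ev_up	hsa-miR-216b-5p
nsc_ev_up	hsa-miR-34a-5p
nsc_ev_up	hsa-miR-1825
nsc_ev_up	hsa-miR-564
nsc_ev_up	hsa-miR-663b
nsc_ev_up	hsa-miR-1300
nsc_ev_up	placeholder-nscEV-01
nsc_ev_up	placeholder-nscEV-02
nsc_ev_up	placeholder-nscEV-03
nsc_ev_up	placeholder-nscEV-04
nsc_ev_up	placeholder-nscEV-05
nsc_ev_up	placeholder-nscEV-06
nsc_ev_up	placeholder-nscEV-07
nsc_ev_higher_than_in	hsa-miR-217
nsc_ev_higher_than_in	hsa-miR-216a-5p
nsc_ev_higher_than_in	hsa-miR-216b-5p
nsc_ev_higher_than_in	hsa-miR-34a-5p
nsc_ev_higher_than_in	hsa-miR-1825
nsc_ev_higher_than_in	hsa-miR-564
nsc_ev_higher_than_in	hsa-miR-663b
nsc_ev_higher_than_in	hsa-miR-1300
fpp_ev_higher_than_in	hsa-miR-21-5p
fpp_ev_higher_than_in	hsa-miR-1226-5p
fpp_ev_higher_than_in	hsa-miR-335-5p
universal_ev	hsa-miR-1274A
universal_ev	hsa-miR-1274B
universal_ev	hsa-miR-34a-3p
universal_ev	hsa-miR-661
universal_ev	hsa-miR-886-5p
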