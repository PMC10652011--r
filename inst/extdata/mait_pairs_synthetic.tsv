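alpha_aa	beta_aa	alpha_v	beta_v
CAVMDSNYQLIW	CASSEGGTEAFF	TRAV1-2	TRBV6-4
CAVRDSNYQLIW	CASSDRGTGELFF	TRAV1-2	TRBV20-1
CAVSDSNYQLIW	CASSPGQGSYEQYF	TRAV1-2	TRBV6-1
CAVKDSNYQLIW	CASSLGGAGDTQYF	TRAV1-2	TRBV28
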