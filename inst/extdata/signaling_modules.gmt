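MSI.stem_like_progenitor	inferred:SLAMF6	TCF7	IL2	CD28	SLAMF6
MSI.inflamed_follicular_like	described	CXCR5	BCL6	ICOS
MSI.long_term_immunosurveillance	described	EOMES	TBX21	PRDM1	KLRK1	KLRG1
MSI.tumor_reactive_exhaustion	described	IFNG	LAG3	PDCD1	CTLA4	TIGIT	ENTPD1	HAVCR2	CXCL13	NFATC2
MSI.memory_differentiation	inferred:JAK3	TOX	IL15RA	NFATC3	NFIL3	STAT1	STAT2	JAK3
MSS.long_term_immunosurveillance	described	EOMES	PRDM1	KLRK1	KLRG1	IL2	TNF
MSS.inflamed_follicular_like	described	CXCR5	BCL6	CD28
MSS.inflamed_memory_like	inferred:NFATC1|IL18R1	TOX	PDCD1	CTLA4	NFATC2	NFATC3	NFATC1	SMAD2	SMAD3	SMAD4	STAT1	STAT2	IL15RA	IL18RAP	IL18R1
MSS.ifng_associated_dysfunctional	described	TBX21	YY1	NFIL3	CXCL9	CXCL10
MSS.tolerogenic_cmaf_signaling	described	MAF	ICOS	LAG3	TIGIT	ENTPD1	HAVCR2
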