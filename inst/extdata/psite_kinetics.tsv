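site	sequence	category	kcat_km	vphos_reported
992	DADEYLIPQ	Minor	74.9	8.4
1045	FLQRYSSDP	Minor	NA	NA
1068	PVPEYINQS	Major	65.4	3.3
1086	QNPVYHNQP	Major	12.1	0.3
1101	RDPHYQDPH	-	NA	NA
1114	GNPEYLNTV	Minor	49.8	1.7
1148	DNPDYQQDF	Major	71.2	2.8
1173	ENAEYLRVA	Major	64.0	2.9
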