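name	fwd	rvs	target_variant	expected_bp
P4HB-02	TCACCGAGCAGAGTGTGTCTG	GATGAACAGGATCTTGCCCTTG	P4HB-02	89
P4HB-021	TATCCCACCATCAAGTTCTTCAG	CGACTCCACGTCACCTGTATATT	P4HB-021	148
P4HB-027	GAATATACAGCTGCAGAGTCC	CTTCATCAAACTTCTTAAAG	P4HB-027	211
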