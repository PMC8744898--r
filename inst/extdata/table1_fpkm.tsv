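transcript_id	liver	HepG2
NONHSAT226968.1	0	104.9
NONHSAT013026.2	0	61.3
NONHSAT250607.1	0	39.3
NONHSAT142412.2	0	30.5
NONHSAT115455.2	0	15.0
NONHSAT168790.1	0	13.7
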