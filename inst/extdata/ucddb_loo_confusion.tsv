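subject	tp	fn	fp	tn
UCDDB003	345	49	45	349
UCDDB011	39	5	1	43
UCDDB020	96	3	2	97
UCDDB024	181	14	13	182
UCDDB026	104	17	9	112
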