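# Side-chain and termini pKa values (Bjellqvist set, as used by the
# ProtParam lineage of pI calculators). sign: +1 basic, -1 acidic.
group	pka	sign
C	9.00	-1
D	4.05	-1
E	4.45	-1
H	5.98	1
K	10.00	1
R	12.00	1
Y	10.00	-1
nterm	7.50	1
cterm	3.55	-1
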