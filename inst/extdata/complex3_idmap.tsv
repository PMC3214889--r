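# alias (UniProt accession or ordered locus name) <TAB> standard gene name
alias	canonical
YEL024W	RIP1
P08067	RIP1
YOR065W	CYT1
P07143	CYT1
Q0105	COB
P00163	COB
YBL045C	COR1
P07256	COR1
YPR191W	QCR2
P07257	QCR2
YFR033C	QCR6
P00127	QCR6
YDR529C	QCR7
P00128	QCR7
YJL166W	QCR8
P08525	QCR8
YGR183C	QCR9
P22289	QCR9
YHR001W-A	QCR10
P37299	QCR10
YKL087C	CYT2
Q00873	CYT2
YDR375C	BCS1
P32839	BCS1
YPL215W	CBP3
P21560	CBP3
YGR174C	CBP4
P37267	CBP4
YLR077W	BCA1
Q08023	BCA1
YDR493W	MZM1
Q03429	MZM1
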