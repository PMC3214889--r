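# Complex III (ubiquinol-cytochrome c reductase) input list:
# standard gene name <TAB> role
RIP1	core
CYT1	core
COB	core
COR1	supernumerary
QCR2	supernumerary
QCR6	supernumerary
QCR7	supernumerary
QCR8	supernumerary
QCR9	supernumerary
QCR10	supernumerary
CYT2	assembly_factor
BCS1	assembly_factor
CBP3	assembly_factor
CBP4	assembly_factor
BCA1	assembly_factor
MZM1	assembly_factor
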