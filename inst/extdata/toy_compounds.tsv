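id	name	formula	monoisotopic_mass
cpd1	hexose	C6H12O6	180.06338810244
cpd2	hexose+CH2	C7H14O6	194.07903816658
cpd3	hexose+2CH2	C8H16O6	208.09468823072
cpd4	sterol	C27H46O	386.35486609482
cpd5	xeno1	C8H10N4O2	194.0803755791
cpd6	xeno2	C6H5BrO	171.95237687995
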