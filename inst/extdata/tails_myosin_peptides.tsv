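peptide	protein_description	hl_ratio
DLEESTLQHEATAAALR	myosin heavy chain, fast skeletal muscle	8.3856
IEELEEELEAER	myosin heavy chain, fast skeletal muscle	7.6228
ELETEIEAEQR	myosin heavy chain, fast skeletal muscle	6.6756
ADLSRELEEISER	myosin heavy chain, fast skeletal muscle	4.6963
VRELESEVEAEQR	myosin heavy chain, fast skeletal muscle	4.4234
TLEDQLSEIKSKNDENLR	myosin heavy chain, fast skeletal muscle	3.4527
VQLELNQVKSEIDR	myosin heavy chain, fast skeletal muscle	3.4453
LEDEEEINAELTAKKR	myosin heavy chain, fast skeletal muscle	3.3276
ELESEVEAEQR	myosin heavy chain, fast skeletal muscle	3.1041
ADIAESQVNKLR	myosin heavy chain, fast skeletal muscle	3.0920
EQFEEEQEAKAELQR	myosin heavy chain, fast skeletal muscle	3.0497
QLEEKEALVSQLTR	myosin heavy chain, fast skeletal muscle	3.0294
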