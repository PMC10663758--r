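enzyme	organism	kcat	Km	reference
EG	Trichoderma reesei	40	25	illustrative-default
EG	Aspergillus niger	22	18	illustrative
EG	Talaromyces emersonii	55	40	illustrative
CBH	Trichoderma reesei	12	10	illustrative-default
CBH	Phanerochaete chrysosporium	8	6	illustrative
CBH	Talaromyces emersonii	18	16	illustrative
BGL	Aspergillus niger	900	2.5	illustrative-default
BGL	Trichoderma reesei	450	1.8	illustrative
BGL	Talaromyces emersonii	1200	4	illustrative
XYL	Trichoderma reesei	60	25	illustrative-default
XYL	Aspergillus niger	85	35	illustrative
XYL	Thermomyces lanuginosus	120	50	illustrative
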