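sample,linker,measured_mass_Da,per_drug_mass_Da,dar_uv_published
Trastuzumab,,147836.9,,
Kadcyla,SMCC,150832.2,957.4,3.3
TSMD,SMCC,149577.7,957.4,2.7
TSPD2,SM(PEG)2,151370.0,1048.4,4
TSPD12,SM(PEG)12,149148.6,1488.7,2
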